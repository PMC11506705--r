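>syn|SYNH10|H1.0
AKPALKTTAPPAKSKAEGRTIVKSKGKYSDMIVAAIQAEKAPKNAAKPAAPVKKALKALTSAPAAAGAPAKTPSVNSAKPKKNKAAKSSKKKKAKKLGPAEGEAAKAKSDAAKKPKAPGADAGKLKSGKPERKAPKPAKIPIKASGLKKAKSASGVAKTSRKLVKKAKSAKGPAQEPAKSPSKPQKEKLKKGAA
>syn|SYNH11|H1.1
NLTEAPQTSAAKAEKKSKVNSAAEAASKSEIEPTKRKKPAGPSVSELIVQAASSSKAPVSKAKASEVAPPAAIKQSKTAPTIAASAGAEAAKPAPPNPVTAPTSSPAASEKAIAKVETPKVETTGGIEPKKKKAPKAKPQAAQKKPGPAPAKAAAATKKKSNKVTKKATAAAKGPVVGTASTSASVAVQALTGKGASRKKKKPTSAPPKIKATGG
>syn|SYNH12|H1.2
MSETAPAAPAAAPPAEAKKAKTKPKTKAKKAPPGPPKPNAAPKKGEAKPEGVPVAKEAESVVGRAKVATSKTLKKTVEKDTIKLEPGKKKKQGAANTNSTASAAGATPKPATPEPPVKSNKTVPPIEPPKAAAANAAEKVATGSKGAAPAVPPGLAPSPQLEKKTKKPITAVTALGKVSKTTASEPPATKAPPTVQAAAGPSAAALPKAAAPS
>syn|SYNH13|H1.3
MSETAPLAPTIPAPAEAAKTEAPKLAAVEPKKAILAKVSIVKSKKGDAPSAKIGAKKLQASPASSKAKSAASATQQASAPETAKTVVDNKSNAKSGKAAVSASIATAPPKSPAGGARRPKSPTAVAPSLASKPLKKNGSKAPAQEKKAVPSKAPQKELTTPDSTISASPVGKSPSEAVASAKAARTEAKKPKAEPSKSLENAAADLPAAGKAARSGSATVG
>syn|SYNH14|H1.4
MSETAPAAPAAPAPAEAAPTTPAAPGAKNTATTGKSLSPAGVRQEAEPAVTKTVKKKGPAPKSAAAPAAVKPTAKTVTKPVKGGKLSPKKGEVASSASAPPKLVDLPIKAKSKKKPTLADKATKGKAKTPKVVTPKAKKKSKKSQVKSSTALAQVVAPAAKPKKAVVPPSSAKAAESAKPTPTNVTEKPIKKASKSALAKPATKAISAASKVSVESKSV
>syn|SYNH15|H1.5
AAEAGVTRSKKSAEKAPKKATSKAAATSASAKRPGAKATGPPVSELITKAAPPGSDGQKAAKSAKVAAGGADPKAARKKAARSAKAKAGVSAGNSAQVPKSKGPKKENAETTPVKPASKKPPAVVGAKAQTTKQTKAKAAKPAADVAKSALATGTKNAEKAAAQGPLKPGAPKPAVLKKASKKDVLPESGGKKPKKAKSKIKGISLAPKIKPAAKKLKKSAAKVAK
>syn|SYNH1X|H1X
ARALAASKTPKTPAEKAAAAAARVPEAADKKAPKRTKVVPGKTESAVKKTEAVAKSKAAASPSKATKITKKKSQAAPPSSKKSSTEVTKKKAKKALVQNDTLLQVKAAAKEKPEKSASEAAASAIAVSAAAGKSPVGNIAKAAKLSKASSSPPKKKAGVKAKPAPKKKKTPKKVPTKLAPKDTAKTEIKKKTKPSVVQQKTKGASKAPGPKKG
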