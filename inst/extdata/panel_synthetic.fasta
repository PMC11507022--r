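>Dre_pvalb1_syn
AFAGILSDADISAALAACNAAGTFNLKEFFAKHGLSGKSAYDIKKVFQIIDQDKSGFIEEDELKDFLQNF
KAGMRALTDAETKHFLKSGDSDGDGKIGVDEFTMLVKAA
>Clu_pvalb1_syn
AFAGILADADISAALAAHNAAGTFNLKEFFAKHGLSGDSAYDIKKVFQIIDQDWSGFIEEDELKDFLQNF
KAGMRALTDAETKHKLKSGDSDGDGKIGVDEFTMWVKAA
>Dre_pvalb2_syn
AFAGILSDADIAAALSACGAAGTFNIKEFFAKLGLSGKSAEDIKKVFCIIDQDKSGFIEEDELKHFLQNF
KAGERALTDAETKDFLKYGDSDGDGKIGVDEFTVLVKAA
>Gmo_pvalb2_syn
TFAGIVGDADIAAALSLCGAAGTFNIKEFFAKLGLSGKSAEDIKKVFCIIDQDKSGFIEEDELYHFLQNF
KAGERALTDAETKDFLKYGDSDGQGKIGVDEFTVLVKAA
>Dre_pvalb3_syn
AFAGILSDADITAALNACQAAGTFNPKEFFAKKGLSGKSAVDIKKVFWIIDQDKSGFIEEDELKVFLQNF
KAGGRALTDAETKWFLKHGDSDGDGKIGVDEFTFLVKAA
>Gmo_pvalb3_syn
AFAGILSDADITPARNACQAAGTFNPKEMFAKKGLSGKSAVDIKKVFWIADQDKSGFIEEDELKVFLQNF
KAGGRALTDAETKWALKHIDSDGDGKIGVDEFTFLVKAA
>Cca_pvalb4_ChrA_syn
AFAGILSDADIIAALDACKAAGTFNKKEFFAKSGLSGKSAKDIKKVFMIIDQDKSGFIEEDELKRFLQNF
KAGNRALTDAETKIFLKMGDSDGDGKIGVDEFTSLVKAA
>Dre_pvalb4_syn
AFAGILSDADIIAALDACKAAGTFDKKEFFAKSGLSGKSAKDIKKVFMIIDQDKSGFIEEDELKRFKQNF
KAGNRALTDWETKIFLKMTDSDGRGKIGVDEFTSLVKAQ
>Gmo_pvalb4_syn
AFAGILSDADMIAALDACKAAGTNNKKEFFAKSGLSDKSAKDIKKVFMIIDQDKSGFLEEDELKRFLQNF
KAGNVALTDAETKISLKMGDSDGDGKIGVDEFTSLVKAA
>Dre_pvalb5_syn
AFLGIDSDADILSALQACEAAGARKHKEFFAKVGLSGHSADDIKKVVGIIDQDKSGFIEEDELKLFLQNF
VAGARALTDANTKAFLKAGDSDGDGKIGVDEFGANVKA
>Ola_pvalb5_syn
AFLGIDSDADILSALQAIEAAGARKHKELFAKVGLSGHSADDIKKVVGIIDQDKSGFIEEDELKLFLQNF
VAHARALTDYNTKLFLKAGDSDGLGKIGVDEFGANVKA
>Dre_pvalb10_syn
AFAGILDDAFIVALLHACDAAGTFNHVEMFATVGLSGKSADDIKKVFGIIDQDKSGFIEEDELSLFLQDF
KAGARSLTDAETDAMLKAGDSDGPGKIGVDEFTALVKAA
>Elu_pvalb10_syn
AFAGILDDAFIVWLAHACDAAGTFNHVEMFGTVGLWGKSADDIKKVFGIIDQDKSGFIEEDELSLFLQDF
CAGARSLTDAETDAMLKAGDSDGPGKIGVDEFAALVKAA
>Dre_pvalb6_syn
VQAFILSDYDLMAALKAFVIAATFNHKIFFAKVGLISKSWDKIKAMFGIKDQDRSGFSEEDELKLKLTNF
KAPAEASTDEETKAFLDAYDSDGDGKIGVDEFTALVKAA
>Elu_pvalb6_syn
VQAFILSDYDLMAPLKAFVIAATFNHKIFFAKVGLISKSWDKIKAMFGIKDQDRSGFSEEDELKLKLTNF
VAPAEASTDEETKAKLDSYDSDGQGKIGVDEFTAYVKAA
>Dre_pvalb7_syn
VQAFILSDYDLMAALKAFVIAATFNHKIFFAKVGLISKSWDKIKAMFGIKDQDRSGFSEEDELKLKLTNF
KAPAEASTDEETKAFLDAYDSDGDGKIGVDEFTALVKAA
>Elu_pvalb7_syn
VQAFILNDYDLMAALKAFVIAATFNHDIFFAKVGLISKSWDKIKAMFGIKDQDRSGFSEEDELKLKLTNF
DAPAEASTDEDTKAFLDAYDSDGDGKIGVDEFTCLVKAR
>Dre_pvalb8_syn
KEAYILSDPDDFAALRAPLHAWTFNHKTFFAKVGLQIKSVDYIKLNFGIYDQDISGFTEEDELKLMLCNF
KAYAYAHTDFETKAFLAALDSDGDGKIGVDEFTALVKA
>Elu_pvalb8_syn
KEAYILSDPDDFRALRAPLHAWTFNHKTHFAKVGLQIKSVNYIKLNMGIYDQDISGFTEEDELKLMLCNF
KAYPYAHTDFETCAFLAALDSDGDGKIGVDEFTALVKA
>Dre_pvalb9_syn
KEAYILSDPDDFAALRAPLHAWTFNHKTFFAKVGLQIKSVDYIKLNFGIYDQDISGFTEEDELKLMLCNF
KAYAYAHTDFETKAFLAALDSDGDGKIGVDEFTALVKA
>Elu_pvalb9_syn
KEAYILSDPDDFAALRAPLHAWTFNHITFFAKVGLQIKSVDYIKLNFYIYDQDISGFTEEDELKLMLCNF
KAYAYAHTDFETKAFLAALDSDGVGKIGVDEFLHCVKA
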