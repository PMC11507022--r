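>Clu_h_1_0101
AFAGILSDADITAALNACQAAHTFNPKEFWAKKGNSFKSAVDLKKVFWIIDQDKSGFIEEDELKVFLQNF
KAGGRALTDAETKWFFKHGDSVGDGKCGVDEFTFLVKAA
>Clu_h_1_0201
AFAGIMSDADISAALAACNAAGTFNLKEFFAKHGLSGKSAYDIAKVFQIIDQDKSGFIEEDEIKDFLQNF
KAGMRSLTDAETKHILKSGDSDGDNKIGIDEFTMAVKAA
>Clu_h_1_0301
AFASILSDADIIAALDACKAAGTFNKKRFFAKSGLSGRSAKDIKKVFMIIDQDQGGFIEEDELKRFLQNF
KAGNRALTDAETKIFCTMGDSDGDGKIQVDEFTSLVKAA
>Cten_i_1_0101
AFAGIISDAEIIAALDACKAAGNFNKKEFFAKSPLSGRSAKDIKKVFMIIDQDKSGFIEEDELKRFLQNF
DAGNRALTDADTKIFLKMGDSDGDGKIGKDEFTSLVKAA
>Cyp_c_1_0101
AFAGILSDADITAALNACQAAGTFRPKECFAKKGYSGKSAVDIKKVFWIIDQDKSGFIEKDELKVFAQNF
KAGGRALTDAETKWFLKHGESDGDGKIGVDEYTFLVTAA
>Cyp_c_1_0201
AYAGITSDADIIAALDACKAAGTFNKKEFFAKSSLSGYSAKDIKKVFMIIDQDKSGFIEEDELKRFLQNF
KAGNRALTDAETKIFLKMFDSDGHGKWGVDEFISLVKAA
>Gad_m_1_0101
TFAGIVGDADIAAALSLCGAAGTFNIKEFFAKLGLSGKSAEDIKKVFCIIDQDKSGFIEEDELYHFLQNF
KAGERALTDAETKDFLKYGDSDGQGKIGVDEFTVLVKAA
>Gad_m_1_0102
TFAGIVGDADIAAALSLCGAAGTFNIKEFFAKLGLSGKSAEDIKKVFCIIDQDKSGFIEEDELYHFLQNF
KAGERALTDAETKDFLKYGDSDGQGKIGVDEFTVLVKAR
>Gad_m_1_0201
AFAGILSDADITPARNACQAAGTFNPKEMFAKKGLSGKSAVDIKKVFWIADQDKSGFIEEDELKVFLQNF
KAGGRALTDAETKWALKHIDSDGDGKIGVDEFTFLVKAA
>Gad_m_1_0202
AFAGILSDADITPARNACQAAGTFNPKEMFAKKGLSGKSAVDIKKVFWIADQDKSGFIEEDELKVFLQNF
KAGGRALTDAETKWALKHIDSDGDGKIGVDEFTFLVKAR
>Lat_c_1_0101
AFAGILSDADITAALNACQAAGTFNPKDFFAKKGLSIKSAVDIKKVFWLIDQDKSGFIEEDELKVLLQRF
KAGGKALTDAETKWFLKHGDSDGDGMIGVDEFTFLVKKA
>Lat_c_1_0201
AFAGILGDADIIAALDACKATGTFNKREFMAKSGLSGKSAKDIKEAFMIIDQDKSGFIEEDELKRFLQNF
PAGNRALTDAETKIFLKMGDSDGDDKIGVDEFTSLVKAA
>Lep_w_1_0101
AFAGILSDADISAALAACNAAGTYQLKEFFAKHGLSGKSAYDIKKVFQIIDQDKSGFIEEEELKDYLQSF
KAGMRALTDAKTKHFLKSGDSDGDGKIAADEFTMLVKAA
>Pan_h_1_0101
AFAGILSDADMIAALDACKAAGTFDKKEFFEKSGLSGKSAKDIKKVFMIIDQDKKSFIEEDELKRFLQNF
KAGNRALTDAETKIVLKMGDSDTDGKIGVDEFSSLVKAA
>Pan_h_1_0201
VQAFILRDYDLMARLKAFVIAATFNHKIFFAKVGLISKSWDKIKAMFGIKDQERSGFSEEDELKLKLTKF
KAPAEASTDEENKAFLDGYDSDGDGKIGVEPFTALVKAA
>Ras_k_1_0101
AFAGILSDANIIAALDACKAAGTFNKKEFFIDSGLSGKSAKDIKKVFMIIDQDKSGFIEEDELKRFLQNG
KAGNTALTDGETKIFLKMGDSDADGKIGVDEFTSLVQAA
>Sal_s_1_0101
AFAGCLSDADNIAALDACKAAGTFNKKEFFAKSGCNGKSAKDIKKVFMIIDQDKSGFIEEDELKRFLQNF
KAGNRALTDAKTQIFLKMGDSSGDGKLGVDEFTSLVKAA
>Sar_sa_1_0101
AFAGILSDFDIIAALDACKAAGTFNKKEFFAKSGLRSKQAKDIKKVFMIIDQDKCGFIEEDELKRFLQNF
KAGNRALTPAETKIFLKMGDSDGDGKIGVGEFTSLVKMA
>Sco_s_1_0101
AFAGILSDADIIAALDACKVAETFNKKEFFAKSGLSYKSAKDIKRVFMIIDQDKSGFIEEDLLKRFLQNF
KARNRALTDAETKIFLKMGDSDGDGKIGIDEFASLVKAA
>Seb_m_1_0101
AFAGILSDADMTAALNACQAAGTFDPKEFFEKKGLSGKSAVDIKKVFWIIDQDKKSFIEEDELKVFLQNF
KAGGRALTDAETKWVLKHGDSDTDGKIGVDEFSFLVKAA
>Seb_m_1_0201
AFAGILSEADIIAALDACKAAGTFNKKEFFAKSGLSGKDAKDIKKVFMIIDQRKSGFIEEDPLKRFLENF
KAGNRALTDGQTKIFLKMGDSQGDGKIGVDEFTSLVKAA
>Thu_a_1_0101
AFAGILSDADITCSLNACQAAGTFNPKEFFAKKGLSGKSQVDQKSVFWIIDQDKSGFIEEDELKVFLQNF
KAGGRALTDAETKWFLKHGQSDGDGKIGVDMMTFLVKAA
>Xip_g_1_0101
AFAGILQDADIIAALDACKAAGTFNKKEFFAKSGLSGASAKDIKKVFMIIDEDKSGFIEEDELKRFLQNF
KAGNRALTDAELKIFLKMGDSDGDGKIGVDKATSLVKYE
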