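species	allergen_code	gene_based_name	chromosome_label	seq_id
Clupea harengus	Clu h 1.0101	pvalb3	NA	Clu_h_1_0101
Clupea harengus	Clu h 1.0201	pvalb1	NA	Clu_h_1_0201
Clupea harengus	Clu h 1.0301	pvalb4	NA	Clu_h_1_0301
Ctenopharyngodon idella	Cten i 1.0101	pvalb4	NA	Cten_i_1_0101
Cyprinus carpio	Cyp c 1.0101	pvalb3_(Chr.B12)	NA	Cyp_c_1_0101
Cyprinus carpio	Cyp c 1.0201	pvalb4_(Chr.B3)	NA	Cyp_c_1_0201
Gadus morhua	Gad m 1.0101	pvalb2.01	NA	Gad_m_1_0101
Gadus morhua	Gad m 1.0102	pvalb2.02	NA	Gad_m_1_0102
Gadus morhua	Gad m 1.0201	pvalb3.01	NA	Gad_m_1_0201
Gadus morhua	Gad m 1.0202	pvalb3.02	NA	Gad_m_1_0202
Lates calcarifer	Lat c 1.0101	pvalb3	NA	Lat_c_1_0101
Lates calcarifer	Lat c 1.0201	pvalb4	NA	Lat_c_1_0201
Lepidorhombus whiffiagonis	Lep w 1.0101	pvalb1	NA	Lep_w_1_0101
Pangasianodon hypophthalmus	Pan h 1.0101	pvalb4	NA	Pan_h_1_0101
Pangasianodon hypophthalmus	Pan h 1.0201	pvalb7	Chr.D	Pan_h_1_0201
Rastrelliger kanagurta	Ras k 1.0101	pvalb4	NA	Ras_k_1_0101
Salmo salar	Sal s 1.0101	pvalb4_(Chr.3)	NA	Sal_s_1_0101
Sardinops sagax	Sar sa 1.0101	pvalb4	NA	Sar_sa_1_0101
Scomber scombrus	Sco s 1.0101	pvalb4	NA	Sco_s_1_0101
Sebastes marinus	Seb m 1.0101	pvalb3	NA	Seb_m_1_0101
Sebastes marinus	Seb m 1.0201	pvalb4	NA	Seb_m_1_0201
Thunnus albacares	Thu a 1.0101	pvalb3	NA	Thu_a_1_0101
Xiphias gladius	Xip g 1.0101	pvalb4	NA	Xip_g_1_0101
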