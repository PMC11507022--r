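id	species	lineage	family	chromosome_label
Dre_pvalb1_syn	Danio_rerio_like	Beta2	pvalb1	Chr.A
Clu_pvalb1_syn	Clupea_harengus_like	Beta2	pvalb1	Chr.A
Dre_pvalb2_syn	Danio_rerio_like	Beta2	pvalb2	Chr.B
Gmo_pvalb2_syn	Gadus_morhua_like	Beta2	pvalb2	Chr.B
Dre_pvalb3_syn	Danio_rerio_like	Beta2	pvalb3	Chr.B
Gmo_pvalb3_syn	Gadus_morhua_like	Beta2	pvalb3	Chr.B
Cca_pvalb4_ChrA_syn	Cyprinus_carpio_like	Beta2	pvalb4	Chr.A
Dre_pvalb4_syn	Danio_rerio_like	Beta2	pvalb4	Chr.A
Gmo_pvalb4_syn	Gadus_morhua_like	Beta2	pvalb4	Chr.A
Dre_pvalb5_syn	Danio_rerio_like	Beta2	pvalb5	Chr.A
Ola_pvalb5_syn	Oryzias_latipes_like	Beta2	pvalb5	Chr.A
Dre_pvalb10_syn	Danio_rerio_like	Beta2	pvalb10	Chr.C
Elu_pvalb10_syn	Esox_lucius_like	Beta2	pvalb10	Chr.C
Dre_pvalb6_syn	Danio_rerio_like	Alpha	pvalb6	Chr.C
Elu_pvalb6_syn	Esox_lucius_like	Alpha	pvalb6	Chr.C
Dre_pvalb7_syn	Danio_rerio_like	Alpha	pvalb7	Chr.D
Elu_pvalb7_syn	Esox_lucius_like	Alpha	pvalb7	Chr.D
Dre_pvalb8_syn	Danio_rerio_like	Oncomodulin	pvalb8	Chr.A
Elu_pvalb8_syn	Esox_lucius_like	Oncomodulin	pvalb8	Chr.A
Dre_pvalb9_syn	Danio_rerio_like	Oncomodulin	pvalb9	Chr.B
Elu_pvalb9_syn	Esox_lucius_like	Oncomodulin	pvalb9	Chr.B
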