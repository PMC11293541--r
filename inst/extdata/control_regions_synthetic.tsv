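chrom	start	end	name	wm
chr13	6459215	6460694	hyperctrl_01	0.9348
chr14	6892693	6894003	hyperctrl_02	0.8848
chr7	12347148	12349932	hyperctrl_03	0.9801
chr1	19053296	19055305	hyperctrl_04	0.9515
chr7	35693776	35696679	hyperctrl_05	0.9525
chr12	51142780	51143710	hyperctrl_06	0.9874
chr22	54574968	54576165	hyperctrl_07	0.8771
chr20	63024758	63025934	hyperctrl_08	0.922
chr19	66961746	66963964	hyperctrl_09	0.9796
chr4	72612738	72614767	hyperctrl_10	0.9156
chr12	87206813	87209791	hyperctrl_11	0.9435
chr22	90573506	90575149	hyperctrl_12	0.9851
chr12	93487021	93488924	hyperctrl_13	0.8802
chr14	106930774	106932436	hyperctrl_14	0.922
chr7	114217013	114219654	hyperctrl_15	0.9011
chr5	119279040	119280245	hyperctrl_16	0.9175
chr11	128408011	128410466	hyperctrl_17	0.9121
chr14	128422117	128423068	hyperctrl_18	0.8983
chr7	160182021	160183168	hyperctrl_19	0.938
chr2	176464293	176466279	hyperctrl_20	0.9008
chr19	184051158	184054116	hyperctrl_21	0.8983
chr7	186096390	186098188	hyperctrl_22	0.915
chr19	188383600	188385303	hyperctrl_23	0.9172
chr5	193978544	193980174	hyperctrl_24	0.9383
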