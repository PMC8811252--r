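gene_id	start	end
GWD1	9902080	9902337
GWD1	9903053	9903094
GWD1	9903210	9903319
GWD1	9903416	9903494
GWD1	9903585	9903676
GWD1	9903758	9903911
GWD1	9904899	9905123
GWD1	9905242	9905583
GWD1	9905676	9905783
GWD1	9905896	9905994
GWD1	9906315	9906455
GWD1	9906583	9906671
GWD1	9907205	9907339
GWD1	9907551	9907713
GWD1	9907822	9907911
GWD1	9907986	9908171
GWD1	9909578	9909640
GWD1	9909715	9909777
GWD1	9909857	9909916
GWD1	9910010	9910162
GWD1	9910280	9910363
GWD1	9911005	9911181
GWD1	9911267	9911373
GWD1	9911740	9911953
GWD1	9912034	9912137
GWD1	9912482	9912614
GWD1	9912751	9912876
GWD1	9913879	9913989
GWD1	9914293	9914391
GWD1	9914746	9914919
GWD1	9915193	9915285
GWD1	9915518	9915633
GWD1	9915990	9916194
DMR6-1	46335699	46335896
DMR6-1	46335367	46335614
DMR6-1	46330610	46330934
DMR6-1	46330195	46330437
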