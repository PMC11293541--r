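control_regions_synthetic.tsv

A SYNTHETIC 24-region stably-hypermethylated control table (chrom, start,
end, name, wm; 0-based half-open coordinates). It mirrors the structure of
the control-region tables used for two-point calibration of
limited-deamination libraries: per region, `wm` is the mean methylation of
the region across public WGBS datasets. Coordinates and wm values here are
randomly generated placeholders for examples and interface tests; they do
not correspond to real genomic control regions. Load with
ramlseq::read_control_table().
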