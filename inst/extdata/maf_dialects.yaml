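# Column maps from MAF dialects to the internal variant schema.
# version bumps are breaking changes for stored fixtures.
version: 1
dialects:
  generic:
    sample_id: sample_id
    gene: gene
    chrom: chrom
    pos: pos
    ref_allele: ref_allele
    alt_allele: alt_allele
    variant_type: variant_type
    variant_classification: variant_classification
    filter_status: filter_status
    callers: callers
    t_depth: t_depth
    t_alt_count: t_alt_count
    n_depth: n_depth
    n_alt_count: n_alt_count
    protein_change: protein_change
    context_seq: context_seq
    context_offset: context_offset
  tcga_mc3:
    sample_id: Tumor_Sample_Barcode
    gene: Hugo_Symbol
    chrom: Chromosome
    pos: Start_Position
    ref_allele: Reference_Allele
    alt_allele: Tumor_Seq_Allele2
    variant_type: Variant_Type
    variant_classification: Variant_Classification
    filter_status: FILTER
    callers: CENTERS
    t_depth: t_depth
    t_alt_count: t_alt_count
    n_depth: n_depth
    n_alt_count: n_alt_count
    protein_change: HGVSp_Short
    context_seq: CONTEXT
    context_offset: CONTEXT_OFFSET
  nhgri:
    sample_id: sample
    gene: gene
    chrom: chrom
    pos: pos
    ref_allele: ref
    alt_allele: alt
    variant_type: type
    variant_classification: classification
    filter_status: filter
    callers: callers
    t_depth: tumor_depth
    t_alt_count: tumor_alt_reads
    n_depth: normal_depth
    n_alt_count: normal_alt_reads
    protein_change: protein_change
    context_seq: context_seq
    context_offset: context_offset
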