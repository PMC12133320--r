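# Reference ranges for pipeline QC metrics.
#
# These defaults are placeholders, NOT derived from any curated MPRA
# dataset collection: calibrate them against your own historical runs
# and edit freely. `risk` says which violation is flagged:
#   below — values under `low` are risky
#   above — values over `high` are risky
#   both  — either violation is risky
# Omit `low`/`high` (or use .inf / -.inf) for unbounded sides.

frac_oligos_qualified:
  low: 0.8
  risk: below
  recommendation: >-
    Fewer oligos than expected retain enough barcodes. Check oligo
    synthesis quality and cloning efficiency, and consider deeper
    association-mapping sequencing.
median_barcodes_per_oligo:
  low: 5
  high: 500
  risk: both
  recommendation: >-
    Barcode complexity is outside the workable range. Too few barcodes
    per oligo inflates activity noise (re-clone with a higher
    barcode:oligo ratio); too many dilutes per-barcode depth downstream
    (bottleneck the library before the reporter insertion).
frac_reads_merged:
  low: 0.7
  risk: below
  recommendation: >-
    Many read pairs failed to merge. Verify the expected fragment length
    against the read length (insufficient overlap), and check adapter or
    quality problems on the association-mapping run.
frac_reads_matched:
  low: 0.5
  risk: below
  recommendation: >-
    Many merged fragments did not match a designed oligo. Check the
    reference FASTA (full oligo vs. variable region; trim offsets), the
    configured flank sequences, and synthesis error rates.
frac_mapped_barcodes_detected:
  low: 0.5
  risk: below
  recommendation: >-
    A large share of mapped barcodes was not seen in this sample.
    Increase sequencing depth or check plasmid library construction;
    inspect the saturation curve to see whether deeper sequencing would
    help. For RNA samples, low coverage with adequate DNA coverage most
    often reflects insufficient RNA input into reverse transcription.
frac_oligos_detected:
  low: 0.8
  risk: below
  recommendation: >-
    Some oligos have no detected barcode at all in this sample; their
    activity cannot be quantified. Increase depth or library complexity.
mean_detection_count:
  low: 10
  risk: below
  recommendation: >-
    Barcodes are detected too few times on average for stable counts;
    sequence deeper or reduce library complexity.
frac_reads_unmapped:
  high: 0.5
  risk: above
  recommendation: >-
    Many counted barcodes are absent from the association map. Check
    barcode orientation/read structure for this step, and whether the
    association-mapping run saturated barcode discovery.
dna_rna_pearson_r:
  high: 0.8
  risk: above
  recommendation: >-
    RNA abundance tracks plasmid abundance too closely, suggesting
    plasmid DNA was not effectively removed before reverse
    transcription. Repeat DNase treatment and verify removal by qPCR.
frac_oligos_quantified:
  low: 0.8
  risk: below
  recommendation: >-
    Many oligos were dropped at quantification (no usable barcodes or
    below the minimum barcode count). Revisit coverage in the DNA
    sample and the min_barcodes / min_dna_count filters.
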