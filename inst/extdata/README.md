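# Bundled data

* `kk3_repeat_summary.tsv` — published per-class repeat-annotation
  summary of the KK3 commercial sugarcane assembly (element counts,
  masked bp and percent of the 7 Gb genome per repeat class). Used by
  the summary-arithmetic checks; totals are always recomputed from the
  per-class rows.
* `kk3_sugar_transporters.tsv` — published sugar-transporter
  gene-family counts for KK3 and the *S. spontaneum* reference.
  Family totals are recomputed by `familyCountTable()`.
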