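# Configuration reproducing the published analysis on the packaged data.
# input: null means the packaged nine-study table.
input: null
models: [allele, homozygous, heterozygous, dominant, recessive]
weights: mh
beta_per_allele: 0.158   # SD ln-Hcy per T allele (GWAS meta-analysis)
r2: 0.01                 # exposure variance explained by the instrument
alpha: 0.05
power: 0.80
tsa:
  model: allele
  rri: 0.1681            # relative risk increase (= pooled allele OR - 1)
  d2: 0.67               # diversity; 'auto' recomputes it from the data
  control_event_proportion: null   # null: control T-allele frequency
  variant: per_group
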