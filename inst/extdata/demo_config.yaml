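# Fully synthetic end-to-end demonstration of the pipeline.
# Run with:
#   library(DevoProteomics)
#   runPipeline(system.file("extdata", "demo_config.yaml",
#                           package = "DevoProteomics"),
#               outputDir = "demo_run")
#
# Every stage draws its randomness from `seed`; a rerun with the same
# config reproduces identical numeric outputs.
seed: 17

spikein:
  nStandards: 48          # UPS2-style staggered standards
  nSampleProteins: 500
  slope: 1.0
  intercept: 3.0          # log10 signal units
  noiseSd: 0.2            # log10 measurement noise
  dynamicRangeOrders: 8   # deep egg proteome dynamic range

absquant:
  totalConcentrationM: 2.0e-3   # scale concentrations to 2 mM total
  cutoffM: 1.0e-8               # 0.01 uM low-concentration cutoff

complexes:
  nComplexes: 20
  subunitsPerComplex: 5
  withinSd: 0.1           # tight within-complex log10 spread
  globalSd: 1.0           # background proteome log10 spread
  nBackground: 100
  alpha: 0.01

twoSpecies:
  nOrthologs: 300
  nStagesA: 8             # ascidian-style eight-stage series
  nStagesB: 8
  shape: inverse_hourglass
  effectSize: 1.0
  noiseSd: 0.05
  metric: pearson
  kCoCluster: 5

dynamics:
  k: 8
  nRestarts: 100

rnaProtein:
  nPairs: 300

orthology:
  nDecoys: 20
  evalueMax: 0.01

snp:
  nSequences: 300
  meanLength: 120
  snpRate: 0.001
  protease: trypsin
  missedCleavages: 0
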