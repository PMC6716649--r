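#!/usr/bin/env Rscript
# Regenerates the packaged fixtures under inst/extdata from the synth
# module. Run from the repository root after changing any generator:
#   Rscript scripts/make_fixtures.R
# The fixtures are committed text files; this script is the single
# calibration point for all synthetic inputs (see the methods vignette).

pkg <- normalizePath(".")
for (f in list.files(file.path(pkg, "R"), full.names = TRUE)) source(f)

out <- file.path(pkg, "inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synth_spec(seed = 20260911L)

w <- function(df, name) {
  utils::write.csv(df, file.path(out, name), row.names = FALSE)
  cat("wrote", name, nrow(df), "rows\n")
}

w(gen_gene_mix(40:85), "gene_mix_by_age.csv")
w(gen_prevalence_by_age(40:85, anchor = 0.039, slope = 0.07),
  "prevalence_by_age.csv")
w(gen_ec_mortality_sporadic(40:100), "ec_mortality_sporadic.csv")
w(gen_crc_incidence_ls(25:100), "crc_incidence_ls.csv")
w(gen_crc_incidence_general(25:100), "crc_incidence_general.csv")
w(gen_crc_mortality_general(25:100), "crc_mortality_general.csv")
w(gen_crc_costs(25:100), "crc_costs.csv")
w(gen_utility_norms(25:100), "utilities.csv")
w(gen_life_table(spec), "life_table.csv")
w(gen_ec_age_distribution(spec, 40:85), "ec_age_distribution.csv")
w(gen_relative_age_distribution(), "relative_age_distribution.csv")
# relative EC incidence curves backing gene_mix_at_age (evidence module)
w(gen_ec_incidence_curves(), "ec_incidence_curves.csv")

# published base-case incremental results (population of 1000 probands and
# 6000 relatives), used for the printed-arithmetic acceptance targets
w(data.frame(
  analysis = rep(c("base_case", "psa"), each = 5),
  strategy = rep(c("MSI_METH", "DIRECT", "IHC_METH", "MSI", "IHC"), 2),
  inc_qalys_vs_none = c(34.5, 35.1, 37.9, 38.3, 40.2,
                        37.6, 38.0, 41.4, 42.7, 45.1),
  inc_cost_vs_none_gbp = c(545000, 769000, 538000, 771000, 826000,
                           573000, 767000, 554000, 855000, 923000)),
  "published_increments.csv")

cat("done\n")
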