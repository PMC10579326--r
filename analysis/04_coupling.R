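#!/usr/bin/env Rscript
# Stage 4 -- stoichiometric coupling to primary production.
#
# Methylphosphonate demethylation liberates CH4 and phosphate 1:1, so each
# net methane formation rate doubles as a phosphate supply rate. Against
# the Redfield phosphate demand (C:P = 106) of the surface median carbon
# fixation rate of 371 nmol C L-1 d-1, the surface rates give the percent
# of primary production supportable by phosphonate-derived phosphorus.

suppressMessages(library(mpnmethane))

cfix <- 371   # surface median carbon fixation, nmol C L-1 d-1
rates <- read.delim("results/rates.tsv")
surf <- rates$net_rate[rates$treatment == "MPn" &
                         rates$depth_category == "surface"]

coup <- support_distribution(surf, cfix, c_to_p = 106)
tab <- data.frame(cfix_rate = cfix, c_to_p = 106,
                  pi_demand = coup$pi_demand, n = coup$n, t(coup$summary))
write_tsv(tab, "results/coupling.tsv")

cat(sprintf("Redfield Pi demand of %d nmol C L-1 d-1: %.1f nmol P L-1 d-1\n",
            cfix, coup$pi_demand))
cat(sprintf("percent support over %d surface incubations: %.1f-%.1f%%, median %.0f%%\n",
            coup$n, coup$summary["min"], coup$summary["max"],
            coup$summary["median"]))
cat(sprintf("(worked example at the printed median rate 0.40: %.0f%%)\n",
            percent_support(0.40, redfield_pi_demand(cfix))))
cat("wrote results/coupling.tsv\n")
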