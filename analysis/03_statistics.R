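#!/usr/bin/env Rscript
# Stage 3 -- depth and treatment statistics.
#
# Nonparametric comparison stack on the net rates: Shapiro-Wilk gate,
# Kruskal-Wallis across the four depths for the reference (MPn) treatment,
# pairwise one-sided Wilcoxon tests with Benjamini-Hochberg adjustment,
# and one-sided treatment contrasts within each depth (Pi co-addition
# tested for repression, nitrate co-addition for enhancement). Zero rates
# (insignificant/exponential incubations) stay in the groups.

suppressMessages(library(mpnmethane))

rates <- read.delim("results/rates.tsv")
mpn <- rates[rates$treatment == "MPn", ]

sw <- shapiro_wilk(mpn$net_rate)
cat(sprintf("Shapiro-Wilk on MPn rates: W = %.3f, p = %.2g -> %s\n",
            sw$W, sw$p,
            if (sw$p < 0.05) "nonparametric path" else "surprisingly normal"))

groups <- split(mpn$net_rate, factor(mpn$depth_category,
                                     levels = depth_levels()))
kw <- kruskal_wallis(groups)
cat(sprintf("Kruskal-Wallis across depths: H = %.1f, df = %d, p = %.2g\n",
            kw$H, kw$df, kw$p))
pw <- pairwise_wilcoxon_bh(groups, alternative = "greater")

write_tsv(data.frame(test = "kruskal_wallis_depths", H = kw$H, df = kw$df,
                     p = kw$p, n = kw$n), "results/stats_kw.tsv")
write_tsv(pw$pairs, "results/stats_pairwise_depth.tsv")

rows <- list()
for (tr in c(MPn_Pi = "less", MPn_NO3 = "greater")) NULL
dirs <- c(MPn_Pi = "less", MPn_NO3 = "greater")
for (tr in names(dirs)) {
  for (dp in depth_levels()) {
    g_tr <- rates$net_rate[rates$treatment == tr &
                             rates$depth_category == dp]
    g_ref <- mpn$net_rate[mpn$depth_category == dp]
    p <- pairwise_wilcoxon_bh(setNames(list(g_tr, g_ref), c(tr, "MPn")),
                              alternative = dirs[[tr]])$pairs$p_raw
    rows[[paste(tr, dp)]] <- data.frame(treatment = tr, depth_category = dp,
                                        alternative = dirs[[tr]], p_raw = p)
  }
}
treat <- do.call(rbind, rows)
treat$p_adjusted <- p.adjust(treat$p_raw, method = "BH")
write_tsv(treat, "results/stats_treatments.tsv")

cat("\ntreatment contrasts vs MPn (BH-adjusted):\n")
print(treat[c("treatment", "depth_category", "p_adjusted")],
      row.names = FALSE)
cat("wrote results/stats_{kw,pairwise_depth,treatments}.tsv\n")
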