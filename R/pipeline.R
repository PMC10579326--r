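#' Assemble a study run configuration
#'
#' Collects every tunable the pipeline consumes: the simulator settings,
#' the significance filter, the stoichiometric constants, and the
#' one-sided test directions for the treatment comparisons. All thresholds
#' are surfaced here; none are hard-coded downstream.
#'
#' @param output_dir Directory for stage outputs (created if missing).
#' @param seed Integer seed for the whole run.
#' @param sim A [simulation_config()] (its seed is overridden by `seed`).
#' @param p_max,r2_min,n_fit_points,exp_ratio,detection_sd Significance
#'   filter (see [classify_rate()]).
#' @param c_to_p Redfield molar C:P ratio.
#' @param cfix_rate Surface carbon fixation rate fed to the coupling
#'   stage, nmol C L^-1 d^-1 (default 371, the study-site surface median).
#' @param identity_threshold Mapping identity threshold, percent.
#' @param treatment_directions Named character vector mapping amended
#'   treatments to the one-sided alternative of treatment-vs-reference:
#'   `"less"` tests repression, `"greater"` enhancement.
#' @param gene_panel Gene panel for the simulated count table.
#' @param total_reads Simulated sequencing depth.
#' @return List of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1L,
                       sim = simulation_config(seed = seed),
                       p_max = 0.05, r2_min = 0.81, n_fit_points = 4,
                       exp_ratio = 3, detection_sd = 0.01,
                       c_to_p = 106, cfix_rate = 371,
                       identity_threshold = 80,
                       treatment_directions = c(MPn_Pi = "less",
                                                MPn_NO3 = "greater"),
                       gene_panel = default_gene_panel(),
                       total_reads = 2e5) {
  sim$seed <- seed
  structure(as.list(environment()), class = "run_config")
}

#' Run the full study pipeline
#'
#' Executes simulate -> rates -> statistics -> coupling -> marker genes on
#' one seeded synthetic campaign, writing a tidy TSV per stage plus a JSON
#' manifest (config echo, seed, per-treatment incubation counts, row
#' counts and md5 checksums of every output). Reruns with the same config
#' are byte-identical.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_study <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  set.seed(config$seed)
  out <- list()
  files <- character()

  ## stage 1: simulate
  say("simulate: campaign of ", config$sim$n_stations, " stations x 4 depths x ",
      config$sim$n_replicates, " replicates x 4 treatments")
  camp <- simulate_campaign(config$sim)
  counts <- simulate_count_table(config$gene_panel, config$total_reads)
  files["incubations"] <- write_tsv(
    incubations_to_table(camp$records),
    file.path(config$output_dir, "incubations.tsv"))
  files["true_rates"] <- write_tsv(
    camp$rates, file.path(config$output_dir, "true_rates.tsv"))
  files["nutrients"] <- write_tsv(
    camp$nutrients, file.path(config$output_dir, "nutrients.tsv"))
  files["gene_counts"] <- write_tsv(
    counts, file.path(config$output_dir, "gene_counts.tsv"))

  ## stage 2: rates
  say("rates: significance filter p < ", config$p_max, ", R^2 > ",
      config$r2_min)
  rates <- estimate_rates(camp$records, n_fit_points = config$n_fit_points,
                          p_max = config$p_max, r2_min = config$r2_min,
                          exp_ratio = config$exp_ratio,
                          detection_sd = config$detection_sd)
  files["rates"] <- write_tsv(rates,
                              file.path(config$output_dir, "rates.tsv"))

  ## stage 3: statistics (reference treatment, across depths; and
  ## amended treatments against the reference within each depth)
  say("stats: Kruskal-Wallis across depths; pairwise one-sided Wilcoxon, BH")
  mpn <- rates[rates$treatment == "MPn", ]
  depth_groups <- split(mpn$net_rate, factor(mpn$depth_category,
                                             levels = depth_levels()))
  kw <- kruskal_wallis(depth_groups)
  pw_depth <- pairwise_wilcoxon_bh(depth_groups, alternative = "greater")
  treat_rows <- list()
  for (tr in names(config$treatment_directions)) {
    for (dp in depth_levels()) {
      g_ref <- rates$net_rate[rates$treatment == "MPn" &
                                rates$depth_category == dp]
      g_tr <- rates$net_rate[rates$treatment == tr &
                               rates$depth_category == dp]
      alt <- unname(config$treatment_directions[[tr]])
      res <- pairwise_wilcoxon_bh(stats::setNames(list(g_tr, g_ref),
                                                  c(tr, "MPn")),
                                  alternative = alt)
      treat_rows[[paste(tr, dp)]] <- data.frame(
        treatment = tr, depth_category = dp, alternative = alt,
        p_raw = res$pairs$p_raw[1], stringsAsFactors = FALSE)
    }
  }
  treat_tab <- do.call(rbind, treat_rows)
  treat_tab$p_adjusted <- stats::p.adjust(treat_tab$p_raw, method = "BH")
  rownames(treat_tab) <- NULL
  kw_tab <- data.frame(test = "kruskal_wallis_depths", H = kw$H, df = kw$df,
                       p = kw$p, n = kw$n)
  files["stats_kw"] <- write_tsv(kw_tab,
                                 file.path(config$output_dir, "stats_kw.tsv"))
  files["stats_pairwise_depth"] <- write_tsv(
    cbind(comparison = rownames(pw_depth$p_adjusted)[
      row(pw_depth$p_adjusted)[lower.tri(pw_depth$p_adjusted)]],
      versus = colnames(pw_depth$p_adjusted)[
        col(pw_depth$p_adjusted)[lower.tri(pw_depth$p_adjusted)]],
      p_adjusted = pw_depth$p_adjusted[lower.tri(pw_depth$p_adjusted)]),
    file.path(config$output_dir, "stats_pairwise_depth.tsv"))
  files["stats_treatments"] <- write_tsv(
    treat_tab, file.path(config$output_dir, "stats_treatments.tsv"))

  ## stage 4: stoichiometric coupling (surface, reference treatment)
  say("coupling: Redfield C:P = ", config$c_to_p, ", carbon fixation ",
      config$cfix_rate, " nmol C L^-1 d^-1")
  surf <- rates$net_rate[rates$treatment == "MPn" &
                           rates$depth_category == "surface"]
  coup <- support_distribution(surf, config$cfix_rate, config$c_to_p)
  coup_tab <- data.frame(
    cfix_rate = config$cfix_rate, c_to_p = config$c_to_p,
    pi_demand = coup$pi_demand, n = coup$n,
    t(coup$summary))
  files["coupling"] <- write_tsv(coup_tab,
                                 file.path(config$output_dir, "coupling.tsv"))

  ## stage 5: marker genes
  say("genes: TPM and recA-normalized phnJ abundance")
  gene_tab <- tpm(counts)
  phnj <- phnj_relative_abundance(counts)
  files["genes_tpm"] <- write_tsv(gene_tab,
                                  file.path(config$output_dir, "genes_tpm.tsv"))
  files["genes_phnj"] <- write_tsv(
    data.frame(phnj_percent_of_genomes = phnj),
    file.path(config$output_dir, "genes_phnj.tsv"))

  ## manifest
  per_treatment <- table(camp$rates$treatment)
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("mpnmethane")),
    thresholds = list(p_max = config$p_max, r2_min = config$r2_min,
                      n_fit_points = config$n_fit_points,
                      exp_ratio = config$exp_ratio,
                      detection_sd = config$detection_sd,
                      c_to_p = config$c_to_p,
                      identity_threshold = config$identity_threshold),
    incubations_per_treatment = as.list(per_treatment),
    files = lapply(stats::setNames(nm = names(files)), function(k) {
      list(path = basename(files[[k]]),
           md5 = unname(tools::md5sum(files[[k]])),
           n_rows = length(readLines(files[[k]])) - 1L)
    })
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done: ", length(files) + 1L, " files in ", config$output_dir)

  invisible(list(campaign = camp, rates = rates,
                 stats = list(kruskal_wallis = kw,
                              pairwise_depth = pw_depth,
                              treatments = treat_tab),
                 coupling = coup, genes = list(tpm = gene_tab, phnj = phnj),
                 manifest = manifest, manifest_path = manifest_path))
}
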