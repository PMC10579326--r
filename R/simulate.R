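#' Configuration of the forward incubation simulator
#'
#' Bundles everything needed to forward-simulate one closed-vessel tracer
#' incubation through the sampling protocol: true production kinetics,
#' vessel geometry, sampling schedule and measurement noise. Defaults
#' mirror the standard campaign design: 250 mL bottle with a 50 mL
#' headspace, 5 mL subsamples at 0/6/12/24/48 h, 1 umol/L
#' 13C-methylphosphonate (labelling fraction 1).
#'
#' @param seed Integer seed (used by [simulate_incubation()] when
#'   `set_seed = TRUE`).
#' @param true_rate True methane production, nmol CH4 L^-1 d^-1 (linear
#'   scenario).
#' @param noise_sd_excess Gaussian measurement noise on the excess scale,
#'   nmol L^-1 (default 0.02).
#' @param scenario `"linear"`, `"exponential"` (late onset) or `"null"`.
#' @param oxidation_k First-order methane loss inside the vessel, d^-1
#'   (default 0; no oxidation correction is ever applied downstream, so a
#'   positive value demonstrates the resulting underestimation).
#' @param geometry A [vessel_geometry()].
#' @param schedule Sampling times in hours, starting at 0.
#' @param labelling_fraction Label fraction of the substrate pool.
#' @param background_ch4_nmol Natural methane in the vessel at t0, nmol
#'   (headspace + dissolved; default 5, about what an air-equilibrated
#'   250 mL bottle holds).
#' @param exp_onset_h,exp_doubling_h,exp_amplitude Late-onset scenario:
#'   production is zero until `exp_onset_h`, then
#'   `amplitude * (2^((t - onset)/doubling) - 1)` nmol L^-1.
#' @param noise_on `"excess"` (default; noise enters the reconstructed
#'   excess scale) or `"atom_fraction"` (noise added to the measured atom
#'   fraction directly).
#' @param noise_sd_atom Atom-fraction noise sd for
#'   `noise_on = "atom_fraction"`.
#' @param depth_medians Named vector of true median rates per depth
#'   category for [simulate_station_profiles()]; defaults are the study
#'   medians 0.40/0.30/0.07/0.06 nmol CH4 L^-1 d^-1.
#' @param lognormal_sigma Log-scale spread of rates around their depth
#'   median (default 1.36, matching a 0.21-1.31 interquartile range around
#'   a median of 0.40).
#' @param n_stations,n_replicates Campaign design (12 stations, duplicate
#'   incubations).
#' @param pi_repression Multiplier on true rates under equimolar phosphate
#'   addition, applied above and at the DCM (default 0.3; no repression
#'   below the DCM).
#' @param no3_enhancement Multiplier on true rates under nitrate addition
#'   (default 3).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              true_rate = 0.4,
                              noise_sd_excess = 0.02,
                              scenario = c("linear", "exponential", "null"),
                              oxidation_k = 0,
                              geometry = vessel_geometry(),
                              schedule = c(0, 6, 12, 24, 48),
                              labelling_fraction = 1,
                              background_ch4_nmol = 5,
                              exp_onset_h = 12,
                              exp_doubling_h = 3,
                              exp_amplitude = 1 / 15,
                              noise_on = c("excess", "atom_fraction"),
                              noise_sd_atom = 1e-5,
                              depth_medians = c(surface = 0.40,
                                                intermediate = 0.30,
                                                DCM = 0.07,
                                                below_DCM = 0.06),
                              lognormal_sigma = 1.36,
                              n_stations = 12,
                              n_replicates = 2,
                              pi_repression = 0.3,
                              no3_enhancement = 3) {
  scenario <- match.arg(scenario)
  noise_on <- match.arg(noise_on)
  stopifnot(inherits(geometry, "vessel_geometry"),
            noise_sd_excess >= 0, oxidation_k >= 0,
            schedule[1] == 0, all(diff(schedule) > 0),
            all(depth_medians > 0), lognormal_sigma >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

# True cumulative production per litre of incubated water at time t (h).
true_production <- function(config, t_h) {
  switch(config$scenario,
         linear = config$true_rate * t_h / 24,
         null = rep(0, length(t_h)),
         exponential = ifelse(
           t_h <= config$exp_onset_h, 0,
           config$exp_amplitude *
             (2^((t_h - config$exp_onset_h) / config$exp_doubling_h) - 1)))
}

#' Forward-simulate one closed-vessel tracer incubation
#'
#' Produces the measurements a cavity ring-down instrument would report
#' for a vessel following the subsampling protocol: methane produced
#' between samplings (as pure 13CH4) joins a natural-abundance background
#' pool, partitions into the headspace by the equilibrium fraction `f_g`,
#' and each sampling removes a known fraction of the vessel content before
#' replacement with CH4-free air. First-order oxidation, if configured,
#' erodes the accumulated excess between samplings. Ground truth is
#' attached for testing.
#'
#' @param config A [simulation_config()].
#' @param station,depth_category,treatment,replicate Metadata passed to
#'   the record.
#' @param set_seed Seed the global stream from `config$seed` (default
#'   FALSE so callers drawing many incubations manage one stream).
#' @return An [incubation_record()] with attribute `truth`: list of
#'   `true_rate`, `scenario`, `true_excess` (nmol L^-1 at the schedule),
#'   `vessel_excess_nmol` and `removed_excess_nmol` ledgers.
#' @export
simulate_incubation <- function(config, station = "S1",
                                depth_category = "surface",
                                treatment = "MPn", replicate = "A",
                                set_seed = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (set_seed) set.seed(config$seed)
  geom <- config$geometry
  f_g <- headspace_fraction(geom)
  a <- removal_fraction(geom)
  x0 <- natural_atom_fraction()
  sched <- config$schedule
  n <- length(sched)

  P <- true_production(config, sched) * geom$liquid_volume  # nmol, vessel
  C <- config$background_ch4_nmol   # total CH4 in vessel
  M <- x0 * C                       # total 13C-CH4 in vessel
  E <- 0                            # accumulated produced excess (nmol)
  amount <- x <- numeric(n)
  true_excess_l <- numeric(n)
  k_h <- config$oxidation_k / 24    # per hour

  # true_rate is on the excess-13C scale (what the instrument's excess
  # calculation recovers): adding pure 13CH4 raises the excess by
  # (1 - x0) per mole, so the physical methane added is dP / (1 - x0).
  for (i in seq_len(n)) {
    dP <- (if (i == 1) P[1] else P[i] - P[i - 1]) / (1 - x0)
    if (k_h > 0 && i > 1) {
      dt <- sched[i] - sched[i - 1]
      # excess decays first order; production spread over the interval
      decay <- exp(-k_h * dt)
      prod_surviving <- if (k_h > 0 && dP > 0) {
        dP * (1 - decay) / (k_h * dt)
      } else dP
      lost <- (E - E * decay) + (dP - prod_surviving)
      E <- E * decay + prod_surviving
      C <- C + dP - lost
      M <- M + dP - lost
    } else {
      E <- E + dP
      C <- C + dP
      M <- M + dP
    }
    amount[i] <- f_g * C
    x[i] <- M / C
    true_excess_l[i] <- true_production(config, sched[i])

    # subsampling removes fraction a of everything, air replaces it
    C <- C * (1 - a)
    M <- M * (1 - a)
    E <- E * (1 - a)
  }

  # measurement noise
  if (config$noise_on == "excess" && config$noise_sd_excess > 0) {
    eps <- stats::rnorm(n, 0, config$noise_sd_excess)   # nmol L^-1 scale
    x <- x + eps * f_g * geom$liquid_volume / amount
  } else if (config$noise_on == "atom_fraction" && config$noise_sd_atom > 0) {
    x <- x + stats::rnorm(n, 0, config$noise_sd_atom)
  }
  x <- pmin(pmax(x, 0), 1)

  rec <- incubation_record(
    station = station, depth_category = depth_category,
    treatment = treatment, replicate = replicate, geometry = geom,
    labelling_fraction = config$labelling_fraction,
    measurements = data.frame(time_h = sched, ch4_nmol_headspace = amount,
                              atom_fraction_13c = x)
  )
  attr(rec, "truth") <- list(true_rate = config$true_rate,
                             scenario = config$scenario,
                             true_excess = true_excess_l)
  rec
}

#' Natural-abundance 13C atom fraction (VPDB)
#'
#' @param r_vpdb 13C/12C ratio of the VPDB standard.
#' @return Atom fraction, approximately 0.01106.
#' @export
natural_atom_fraction <- function(r_vpdb = 0.0111802) r_vpdb / (1 + r_vpdb)

#' Simulate a campaign's true rate table and nutrient profiles
#'
#' Draws true methane-formation rates for every station x depth x
#' replicate x treatment cell: lognormal around the configured depth
#' medians for methylphosphonate amendments, repressed by
#' `pi_repression` above and at the DCM for equimolar phosphate
#' co-addition, enhanced by `no3_enhancement` for nitrate co-addition, and
#' zero for the DIC-only amendment (aerobic methane formation from DIC is
#' at most sporadic). Also fabricates station nutrient profiles in which
#' phosphate is censored above and at the deep chlorophyll maximum and
#' 100-400 nmol L^-1 below it, and the phosphorus pool identities
#' TP = Pi + DOP + POP hold by construction.
#'
#' Uses the global random stream; call `set.seed()` first (or via
#' [run_study()]) for reproducibility.
#'
#' @param config A [simulation_config()].
#' @return List with `rates` (station, depth_category, treatment,
#'   replicate, true_rate) and `nutrients` (one row per station/depth with
#'   concentrations, censoring flags and LODs).
#' @export
simulate_station_profiles <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  depths <- depth_levels()
  stations <- paste0("S", seq_len(config$n_stations))
  reps <- LETTERS[seq_len(config$n_replicates)]
  grid <- expand.grid(station = stations, depth_category = depths,
                      replicate = reps, stringsAsFactors = FALSE)

  base <- stats::rlnorm(nrow(grid),
                        meanlog = log(config$depth_medians[grid$depth_category]),
                        sdlog = config$lognormal_sigma)
  repress <- ifelse(grid$depth_category == "below_DCM", 1,
                    config$pi_repression)
  rates <- rbind(
    cbind(grid, treatment = "MPn", true_rate = base),
    cbind(grid, treatment = "MPn_Pi", true_rate = base * repress),
    cbind(grid, treatment = "MPn_NO3", true_rate = base *
            config$no3_enhancement),
    cbind(grid, treatment = "DIC", true_rate = 0)
  )
  rates <- rates[c("station", "depth_category", "treatment", "replicate",
                   "true_rate")]
  rownames(rates) <- NULL

  depth_m <- c(surface = 10, intermediate = 45, DCM = 90, below_DCM = 160)
  ng <- expand.grid(station = stations, depth_category = depths,
                    stringsAsFactors = FALSE)
  nn <- nrow(ng)
  above <- ng$depth_category != "below_DCM"
  pi_true <- ifelse(above, stats::runif(nn, 0.2, 8),
                    stats::runif(nn, 100, 400))
  lods <- default_lods()
  pi_cens <- pi_true < lods[["Pi"]]
  dop <- stats::runif(nn, 30, 153)
  pop <- stats::runif(nn, 5, 30)
  nox_true <- ifelse(above, stats::runif(nn, 10, 400), 20 * pi_true)
  nox_cens <- nox_true < lods[["NOx"]]
  nh4_true <- stats::runif(nn, 2, 20)
  nh4_cens <- nh4_true < lods[["NH4"]]
  no2_true <- stats::runif(nn, 1, 25)
  no2_cens <- no2_true < lods[["NO2"]]

  nutrients <- data.frame(
    ng,
    depth_m = depth_m[ng$depth_category],
    Pi = ifelse(pi_cens, NA_real_, pi_true),
    Pi_censored = pi_cens,
    TP = pi_true + dop + pop,
    POP = pop,
    DOP_true = dop,
    NOx = ifelse(nox_cens, NA_real_, nox_true),
    NOx_censored = nox_cens,
    NH4 = ifelse(nh4_cens, NA_real_, nh4_true),
    NH4_censored = nh4_cens,
    NO2 = ifelse(no2_cens, NA_real_, no2_true),
    NO2_censored = no2_cens,
    Pi_true = pi_true,
    stringsAsFactors = FALSE
  )
  list(rates = rates, nutrients = nutrients)
}

#' Simulate incubation records for a whole campaign
#'
#' Wraps [simulate_station_profiles()] and forward-simulates one
#' [incubation_record()] per rate-table row through
#' [simulate_incubation()] (linear scenario at the drawn true rate for
#' methylphosphonate treatments at 100% labelling; null scenario at ~10%
#' labelling for the DIC amendment).
#'
#' @param config A [simulation_config()].
#' @return List with `records` (incubation records), `rates` (the true
#'   rate table) and `nutrients`.
#' @export
simulate_campaign <- function(config) {
  prof <- simulate_station_profiles(config)
  records <- lapply(seq_len(nrow(prof$rates)), function(i) {
    row <- prof$rates[i, ]
    dic <- row$treatment == "DIC"
    cfg <- config
    cfg$true_rate <- row$true_rate
    cfg$scenario <- if (dic || row$true_rate == 0) "null" else "linear"
    cfg$labelling_fraction <- if (dic) 0.1 else 1
    simulate_incubation(cfg, station = row$station,
                        depth_category = row$depth_category,
                        treatment = row$treatment,
                        replicate = row$replicate)
  })
  list(records = records, rates = prof$rates, nutrients = prof$nutrients)
}

#' Simulate a marker-gene count table with known normalization answers
#'
#' Draws read counts multinomially with per-gene probabilities
#' proportional to `rel_rate * orf_length`, so the expected
#' length-normalized rate of each gene is proportional to `rel_rate`: the
#' exact TPM answer is `rel_rate / sum(rel_rate) * 1e6` and the exact phnJ
#' percentage is `100 * sum(rel_rate[phnJ]) / sum(rel_rate[recA])`.
#'
#' @param genes data.frame with columns `gene_id`, `orf_length`,
#'   `taxon_label`, `gene_family`, `rel_rate` (>= 0); see
#'   [default_gene_panel()].
#' @param total_reads Sequencing depth (default 2e5).
#' @return Gene count table with attribute `truth` (list of `tpm` and
#'   `phnj_percent` expected values).
#' @export
simulate_count_table <- function(genes, total_reads = 2e5) {
  stopifnot(all(c("gene_id", "orf_length", "gene_family", "rel_rate")
                %in% names(genes)),
            all(genes$rel_rate >= 0), any(genes$rel_rate > 0))
  prob <- genes$rel_rate * genes$orf_length
  counts <- stats::rmultinom(1, size = total_reads, prob = prob)[, 1]
  out <- data.frame(
    gene_id = genes$gene_id,
    orf_length = genes$orf_length,
    read_count = as.numeric(counts),
    taxon_label = if ("taxon_label" %in% names(genes)) genes$taxon_label
                  else NA_character_,
    gene_family = genes$gene_family,
    stringsAsFactors = FALSE
  )
  truth_tpm <- genes$rel_rate / sum(genes$rel_rate) * 1e6
  reca <- sum(genes$rel_rate[genes$gene_family == "recA"])
  truth_phnj <- if (reca > 0) {
    100 * sum(genes$rel_rate[genes$gene_family == "phnJ"]) / reca
  } else NA_real_
  attr(out, "truth") <- list(tpm = truth_tpm, phnj_percent = truth_phnj)
  out
}

#' Default simulated gene panel
#'
#' One recA representative, a configurable phnJ signal split over a
#' cyanobacterial and two alphaproteobacterial clusters, and a bed of
#' unrelated genes.
#'
#' @param phnj_percent Target phnJ abundance as percent of recA-normalized
#'   genomes (default 14.71).
#' @param n_other Number of background genes.
#' @return data.frame consumable by [simulate_count_table()].
#' @export
default_gene_panel <- function(phnj_percent = 14.71, n_other = 20) {
  phnj_rate <- phnj_percent / 100
  split <- c(0.7, 0.2, 0.1)
  data.frame(
    gene_id = c("recA_c1", paste0("phnJ_c", 1:3),
                paste0("gene_", seq_len(n_other))),
    orf_length = c(1060, 750, 846, 834,
                   round(seq(400, 2200, length.out = n_other))),
    taxon_label = c("Bacteria", "Trichodesmium", "SAR11", "SAR116",
                    rep("Bacteria", n_other)),
    gene_family = c("recA", rep("phnJ", 3), rep("other", n_other)),
    rel_rate = c(1, phnj_rate * split,
                 rep(0.5, n_other)),
    stringsAsFactors = FALSE
  )
}
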