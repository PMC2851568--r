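#' Run one pipeline stage from a flat configuration
#'
#' Dispatches the named subcommand, writes its outputs into `out_dir`, and
#' writes a JSON run log (`run_log.json`) echoing the configuration, the
#' package version, the seed, and per-stage record counts — enough to
#' reproduce the run. Identical configuration and seed give byte-identical
#' outputs.
#'
#' Subcommands and their main parameters:
#' * `simulate-foci`: `model`, `foci_per_zone`, `n_zones`,
#'   `nucleus_diameter_um`, `focus_diameter_nm`, `n_chains`,
#'   `n_keep_chains` (optional segregation), `step_sd_nm` (optional
#'   plasticity) -> `foci.tsv`.
#' * `nn`: `foci` (input TSV), `a_zone`, `b_zone`, `threshold_nm`,
#'   `voxel_nm` -> `distances.tsv`, `nn_summary.json`.
#' * `simulate-clusters`: `n_clusters`, `mu`, `sigma`, `pmf` (e.g.
#'   `"3:1,4:1,5:1"`), `bin_width_kbp` -> `cluster_profile.tsv`,
#'   `cluster_summary.json`.
#' * `simulate-profile`: `n_domains`, `min_length_kbp`, `max_length_kbp`,
#'   `bin_size_bp`, `noise_sd` -> `profile.bedGraph`.
#' * `segment-domains`: `bedgraph` (input), `window`, `min_prominence`,
#'   `min_domain_length_kbp` -> `domains.bed`, `domain_lengths.tsv`.
#' * `simulate-fibers`: `n_fibers`, `noise_sd_kbp`, plus [fiber_config()]
#'   fields -> `fibers.tsv`.
#' * `classify-fibers`: `fibers` (input TSV), `cluster_gap_kbp`,
#'   `exclusion_kbp`, `min_fiber_kbp`, `kbp_per_um`, `pulse1_min` ->
#'   `fiber_classes.tsv`, `fiber_report.json`.
#'
#' @param config Named list with at least `subcommand`; `seed` defaults to 1
#'   and `out_dir` to `"."`. Unknown keys are rejected.
#' @return The run log, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$subcommand)) abort("config$subcommand is required")
  sub <- config$subcommand
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  common <- c("subcommand", "seed", "out_dir")
  allowed <- list(
    "simulate-foci" = c("model", "foci_per_zone", "n_zones",
                        "nucleus_diameter_um", "focus_diameter_nm",
                        "n_chains", "n_keep_chains", "step_sd_nm"),
    "nn" = c("foci", "a_zone", "b_zone", "threshold_nm", "voxel_nm"),
    "simulate-clusters" = c("n_clusters", "mu", "sigma", "pmf",
                            "bin_width_kbp"),
    "simulate-profile" = c("n_domains", "min_length_kbp", "max_length_kbp",
                           "bin_size_bp", "noise_sd"),
    "segment-domains" = c("bedgraph", "window", "min_prominence",
                          "min_domain_length_kbp"),
    "simulate-fibers" = c("n_fibers", "noise_sd_kbp", "pulse1_min",
                          "chase_min", "pulse2_min", "kbp_per_um"),
    "classify-fibers" = c("fibers", "cluster_gap_kbp", "exclusion_kbp",
                          "min_fiber_kbp", "kbp_per_um", "pulse1_min")
  )
  if (!sub %in% names(allowed)) {
    abort(paste0("unknown subcommand: ", sub,
                 "; expected one of ", paste(names(allowed), collapse = ", ")))
  }
  unknown <- setdiff(names(config), c(common, allowed[[sub]]))
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }

  counts <- switch(
    sub,
    "simulate-foci" = {
      cfg <- nucleus_config(
        nucleus_diameter_um = config$nucleus_diameter_um %||% 10,
        focus_diameter_nm = config$focus_diameter_nm %||% 500,
        foci_per_zone = config$foci_per_zone %||% 350,
        n_zones = config$n_zones %||% 10
      )
      fs <- gen_nuclear_foci(cfg, model = config$model %||% "genetic",
                             seed = seed,
                             n_chains = config$n_chains %||% 46L)
      if (!is.null(config$n_keep_chains)) {
        fs <- apply_segregation(fs, config$n_keep_chains, seed = seed + 1L)
      }
      if (!is.null(config$step_sd_nm)) {
        fs <- apply_plasticity(fs, config$step_sd_nm, seed = seed + 2L)
      }
      write_foci_tsv(fs, file.path(out_dir, "foci.tsv"))
      list(foci = nrow(fs))
    },
    "nn" = {
      fs <- read_foci_tsv(config$foci)
      a <- zone_subset(fs, config$a_zone %||% 1L)
      b <- zone_subset(fs, config$b_zone %||% 2L)
      d <- nn_cross_channel(a, b)
      readr::write_tsv(as_tibble(d), file.path(out_dir, "distances.tsv"))
      summ <- summarize_distances(d)
      thr <- config$threshold_nm %||% 500
      res <- list(
        mean = summ$mean_nm, sd = summ$sd_nm, n = summ$n,
        coassociation_fraction = coassociation_fraction(a, b, thr),
        threshold_nm = thr,
        within_a = if (nrow(a) >= 2) {
          as.list(summarize_distances(nn_within_channel(a)))
        },
        colocalization_fraction = if (!is.null(config$voxel_nm)) {
          colocalization_fraction(a, b, config$voxel_nm)
        }
      )
      jsonlite::write_json(res, file.path(out_dir, "nn_summary.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      list(a_foci = nrow(a), b_foci = nrow(b), distances = nrow(d))
    },
    "simulate-clusters" = {
      pmf <- parse_pmf(config$pmf %||% "3:1,4:1,5:1")
      model <- replicon_length_model(mu = config$mu %||% 140.6238,
                                     sigma = config$sigma %||% 58.8192)
      cs <- sample_clusters(config$n_clusters %||% 112L, pmf, model, seed)
      prof <- build_profile(cs$dna_content_kbp,
                            config$bin_width_kbp %||% 50)
      readr::write_tsv(as_tibble(prof),
                       file.path(out_dir, "cluster_profile.tsv"))
      jsonlite::write_json(as.list(glance(prof)),
                           file.path(out_dir, "cluster_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      list(clusters = nrow(cs))
    },
    "simulate-profile" = {
      withr::local_seed(seed)
      nd <- config$n_domains %||% 6L
      lens <- runif(nd, config$min_length_kbp %||% 275,
                    config$max_length_kbp %||% 935)
      heights <- runif(nd, 1, 10)
      p <- gen_timing_profile(lens, heights,
                              bin_size_bp = config$bin_size_bp %||% 10000,
                              noise_sd = config$noise_sd %||% 0,
                              seed = seed)
      write_bedgraph(p, file.path(out_dir, "profile.bedGraph"))
      list(domains = nd, bins = nrow(p))
    },
    "segment-domains" = {
      p <- read_bedgraph(config$bedgraph)
      dom <- call_domains(
        p, window = config$window %||% 3L,
        min_prominence = config$min_prominence,
        min_domain_length_kbp = config$min_domain_length_kbp %||% 0
      )
      write_domains_bed(dom, file.path(out_dir, "domains.bed"))
      readr::write_tsv(dom["length_kbp"],
                       file.path(out_dir, "domain_lengths.tsv"))
      list(bins = nrow(p), domains = nrow(dom))
    },
    "simulate-fibers" = {
      cfg <- fiber_config(
        pulse1_min = config$pulse1_min %||% 30,
        chase_min = config$chase_min %||% 60,
        pulse2_min = config$pulse2_min %||% 20,
        kbp_per_um = config$kbp_per_um %||% 2.59,
        noise_sd_kbp = config$noise_sd_kbp %||% 5
      )
      fb <- gen_fibers(cfg, config$n_fibers %||% 100L, seed)
      write_fibers_tsv(fb, file.path(out_dir, "fibers.tsv"))
      list(fibers = length(unique(fb$fiber_id)), tracks = nrow(fb))
    },
    "classify-fibers" = {
      fb <- read_fibers_tsv(config$fibers)
      params <- fiber_params(
        cluster_gap_kbp = config$cluster_gap_kbp %||% 250,
        exclusion_kbp = config$exclusion_kbp %||% 250,
        min_fiber_kbp = config$min_fiber_kbp %||% 800,
        kbp_per_um = config$kbp_per_um %||% 2.59
      )
      rep <- cohort_report(fb, params,
                           pulse1_min = config$pulse1_min %||% 30)
      readr::write_tsv(rep$classes, file.path(out_dir, "fiber_classes.tsv"))
      jsonlite::write_json(
        list(class_summary = rep$class_summary,
             inter_origin = rep$inter_origin,
             uncoupled_fiber_fraction = rep$uncoupled_fiber_fraction,
             uncoupled_group_fraction = rep$uncoupled_group_fraction,
             n_fibers = rep$n_fibers, n_excluded = rep$n_excluded),
        file.path(out_dir, "fiber_report.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows"
      )
      list(fibers = rep$n_fibers, excluded = rep$n_excluded)
    }
  )

  log <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("nextinline")),
    config = config[setdiff(names(config), "subcommand")],
    subcommand = sub,
    seed = seed,
    record_counts = counts
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(log)
}

# "3:1,4:1,5:2" -> cluster_size_pmf(c(3,4,5), c(1,1,2))
parse_pmf <- function(spec) {
  parts <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) abort("pmf spec must look like '3:1,4:1,5:1'")
  cluster_size_pmf(
    sizes = as.integer(vapply(parts, `[[`, "", 1L)),
    prob = as.numeric(vapply(parts, `[[`, "", 2L))
  )
}
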