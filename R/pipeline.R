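#' Pipeline configuration
#'
#' One flat, serializable record of every tunable the pipeline uses, with
#' the published defaults: 200 bootstrap resamples of 13 individuals for the
#' drift test (flagging at p < 0.02), 1000 pseudo-individual profile
#' resamples, a 3-km grid with the 80-km placement filter and 24-km display
#' jitter, and the 28-year/1940-CE calendar conversion. Round-trips
#' losslessly through JSON.
#'
#' @param seed Integer master seed; every stage derives its stream from it.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "paint", "cluster", "test_drift", "profile", "smooth",
#'   "date")`.
#' @param switch_rate,miscopy Painting parameters ([copying_params()]).
#' @param curve_switch_rate Painting switch rate used for the dating stage
#'   (shorter chunks keep within-chunk artefacts below the curve cutoff).
#' @param c_factor Clustering c-factor (`NULL` = chunk-length heuristic).
#' @param n_burn,n_sample,thin MCMC schedule.
#' @param subsample_size,n_resamples,flag_p Drift-test protocol.
#' @param n_boot_profile Profile bootstrap replicates.
#' @param cell_km,max_gp_km,jitter_km,k_nn,base_bw_km,kernel_km Smoothing and
#'   placement parameters.
#' @param bin_width,min_cm,max_cm,n_null,evidence_p,n_boot_date Dating
#'   parameters.
#' @param generation_time,reference_year Calendar conversion.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("simulate", "paint", "cluster",
                                       "test_drift", "profile", "smooth",
                                       "date"),
                            switch_rate = 0.1, miscopy = 0.01,
                            curve_switch_rate = 2,
                            c_factor = NULL,
                            n_burn = 200L, n_sample = 150L, thin = 2L,
                            subsample_size = 13L, n_resamples = 200L,
                            flag_p = 0.02,
                            n_boot_profile = 1000L,
                            cell_km = 3, max_gp_km = 80, jitter_km = 24,
                            k_nn = 10L, base_bw_km = 3, kernel_km = 20,
                            bin_width = 1, min_cm = 3, max_cm = 50,
                            n_null = 100L, evidence_p = 0.01,
                            n_boot_date = 100L,
                            generation_time = 28, reference_year = 1940) {
  cfg <- as.list(environment())
  bad <- setdiff(cfg$stages, c("simulate", "paint", "cluster", "test_drift",
                               "profile", "smooth", "date"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stopifnot(cfg$flag_p > 0, cfg$flag_p < 1, cfg$evidence_p > 0,
            cfg$subsample_size >= 2, cfg$n_resamples >= 1)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(lst$c_factor) == 0) lst$c_factor <- NULL
  do.call(pipeline_config, lst)
}

#' Default demonstration scenario
#'
#' Three drifted demes on a planar landscape, two external donor pools (one
#' strongly diverged), and a dated pulse from the diverged pool into one
#' deme: the smallest world in which every pipeline stage has signal to find.
#'
#' @param seed Integer seed.
#' @return A [demographic_scenario()].
#' @export
default_scenario <- function(seed = 1L) {
  demographic_scenario(
    demes = tibble::tibble(
      label = c("A", "B", "C"), n = 20L, drift = c(0.2, 0.22, 0.24),
      x_km = c(0, 120, 60), y_km = c(0, 0, 100), dispersion_km = 8),
    donors = tibble::tibble(label = c("P1", "P2"), n = 12L,
                            divergence = c(0.05, 0.5)),
    pulses = tibble::tibble(source = "P2", recipient = "C",
                            alpha = 0.1, g = 30),
    n_chrom = 2L, chrom_cm = 100, snps_per_chrom = 800L, seed = seed)
}

#' Run the full analysis pipeline
#'
#' simulate -> paint -> cluster -> test_drift -> profile -> smooth -> date,
#' writing every artifact as TSV/Newick/JSON under a deterministic directory
#' layout. Rerunning with the same config reproduces every output file
#' byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; stage subdirectories inside).
#' @param scenario A [demographic_scenario()] (default [default_scenario()]
#'   seeded from the config).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         scenario = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(scenario)) scenario <- default_scenario(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sub <- function(d) {
    p <- file.path(out_dir, d)
    dir.create(p, showWarnings = FALSE)
    p
  }
  logd <- sub("logs")
  write_config(config, file.path(logd, "config.json"))
  jsonlite::write_json(list(seed = config$seed,
                            config_hash = rlang::hash(unclass(config)),
                            stages = config$stages),
                       file.path(logd, "run.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  res <- list()
  stage <- function(name) name %in% config$stages
  params <- copying_params(config$switch_rate, config$miscopy)
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (stage("simulate")) run_stage("simulate", {
    sim <- simulate_structured_panel(scenario)
    sim$panel <- assign_geography(sim$panel, scenario,
                                  seed = config$seed + 1L)
    d <- sub("inputs")
    write_hap_sample(sim$panel, file.path(d, "panel"))
    write_genetic_map(sim$panel$map, file.path(d, "map.tsv"))
    write_metadata(sim$panel$samples, file.path(d, "metadata.tsv"))
    write_tracts(sim$truth, file.path(d, "tracts.tsv"))
    res$sim <- sim
  })
  sim <- res$sim
  if (is.null(sim)) stop("pipeline requires the simulate stage in this build",
                         call. = FALSE)
  deme_ids <- sim$panel$samples$id[sim$panel$samples$role == "deme"]
  demes <- panel_subset(sim$panel, deme_ids)
  donors <- panel_subset(sim$panel,
                         sim$panel$samples$id[sim$panel$samples$role == "donor"])

  if (stage("paint")) run_stage("paint", {
    d <- sub("matrices")
    cmx <- coancestry_square(demes, params)
    write_matrix(cmx, file.path(d, "coancestry_square.tsv"))
    restr <- coancestry_restricted(demes, donors, params)
    write_matrix(restr$X, file.path(d, "coancestry_restricted.tsv"))
    write_matrix(restr$X_group, file.path(d, "coancestry_groups.tsv"))
    res$square <- cmx
    res$restricted <- restr
  })

  if (stage("cluster")) run_stage("cluster", {
    d <- sub("clusters")
    fit <- fs_mcmc(res$square, c_factor = config$c_factor,
                   n_burn = config$n_burn, n_sample = config$n_sample,
                   thin = config$thin, seed = config$seed + 2L)
    cert <- assignment_certainty(fit)
    part <- fit$partition
    part$certainty <- cert[cbind(seq_len(nrow(part)), part$cluster)]
    write_partition(part, file.path(d, "partition.tsv"))
    tree <- build_tree(fit)
    write_newick(tree, file.path(d, "tree.nwk"))
    utils::write.table(format_num_df(tree$merges), file.path(d, "merges.tsv"),
                       quote = FALSE, row.names = FALSE, sep = "\t")
    utils::write.table(
      format_num_df(tibble::tibble(sample = seq_along(fit$trace$logpost),
                                   logpost = fit$trace$logpost)),
      file.path(d, "trace.tsv"), quote = FALSE, row.names = FALSE, sep = "\t")
    block <- build_external_sharing_matrix(res$restricted)
    efit <- cluster_on_external_sharing(block, c_factor = config$c_factor,
                                        n_burn = config$n_burn,
                                        n_sample = config$n_sample,
                                        thin = config$thin,
                                        seed = config$seed + 3L)
    write_partition(efit$partition, file.path(d, "external_partition.tsv"))
    res$fit <- fit; res$tree <- tree; res$efit <- efit
  })

  if (stage("test_drift")) run_stage("test_drift", {
    d <- sub("tests")
    part <- if (!is.null(res$fit)) res$fit$partition else
      tibble::tibble(id = demes$samples$id,
                     cluster = as.integer(factor(demes$samples$group)))
    dt <- bootstrap_coancestry_test(demes, part,
                                    subsample_size = config$subsample_size,
                                    n_resamples = config$n_resamples,
                                    params = params, flag_p = config$flag_p,
                                    seed = config$seed + 4L)
    utils::write.table(format_num_df(dt), file.path(d, "drift_test.tsv"),
                       quote = FALSE, row.names = FALSE, sep = "\t")
    res$drift <- dt
  })

  if (stage("profile")) run_stage("profile", {
    d <- sub("profiles")
    B <- donor_basis_vectors(donors, params)
    write_matrix(B, file.path(d, "donor_basis.tsv"))
    part <- if (!is.null(res$fit)) res$fit$partition else
      tibble::tibble(id = demes$samples$id,
                     cluster = as.integer(factor(demes$samples$group)))
    ch <- chromosome_level_vectors(demes, donors, params, by = "group")
    out <- list()
    for (k in sort(unique(part$cluster))) {
      members <- part$id[part$cluster == k]
      if (length(members) < 2) next
      bi <- bootstrap_profile_intervals(ch[members, , , drop = FALSE], B,
                                        n_boot = config$n_boot_profile,
                                        seed = config$seed + 10L + k)
      bi$cluster <- k
      out[[length(out) + 1]] <- bi
    }
    prof <- dplyr::bind_rows(out)
    utils::write.table(format_num_df(prof), file.path(d, "cluster_profiles.tsv"),
                       quote = FALSE, row.names = FALSE, sep = "\t")
    res$profiles <- prof; res$basis <- B; res$chrom_vectors <- ch
  })

  if (stage("smooth")) run_stage("smooth", {
    d <- sub("grids")
    placed <- place_individuals(demes$samples, max_gp_km = config$max_gp_km,
                                jitter_km = config$jitter_km,
                                seed = config$seed + 5L)
    utils::write.table(format_num_df(placed), file.path(d, "placed.tsv"),
                       quote = FALSE, row.names = FALSE, sep = "\t")
    part <- if (!is.null(res$fit)) res$fit$partition else
      tibble::tibble(id = demes$samples$id,
                     cluster = as.integer(factor(demes$samples$group)))
    dens <- cluster_density_grid(placed, part, cell_km = config$cell_km,
                                 kernel_km = config$kernel_km)
    utils::write.table(format_num_df(dens), file.path(d, "cluster_density.tsv"),
                       quote = FALSE, row.names = FALSE, sep = "\t")
    if (!is.null(res$restricted)) {
      sm <- smoothed_copying_grid(placed, res$restricted$X_group,
                                  cell_km = config$cell_km,
                                  base_bw_km = config$base_bw_km,
                                  k_nn = config$k_nn)
      gtab <- dplyr::bind_cols(sm$grid,
                               tibble::as_tibble(as.data.frame(sm$Y)))
      utils::write.table(format_num_df(gtab), file.path(d, "smoothed.tsv"),
                         quote = FALSE, row.names = FALSE, sep = "\t")
      if (!is.null(res$basis)) {
        gp <- grid_profiles(sm, res$basis)
        utils::write.table(format_num_df(gp), file.path(d, "grid_profiles.tsv"),
                           quote = FALSE, row.names = FALSE, sep = "\t")
        res$grid_profiles <- gp
      }
      res$smoothed <- sm
    }
    res$placed <- placed
  })

  if (stage("date")) run_stage("date", {
    d <- sub("dating")
    cparams <- copying_params(config$curve_switch_rate, config$miscopy)
    B <- if (!is.null(res$basis)) res$basis else
      donor_basis_vectors(donors, cparams)
    rec_lab <- unique(scenario$pulses$recipient)
    targets <- if (length(rec_lab))
      demes$samples$id[demes$samples$group %in% rec_lab] else deme_ids
    pp <- paint_posteriors(panel_subset(demes, targets), donors, cparams)
    ev <- infer_two_way_event(pp, B, bin_width = config$bin_width,
                              min_cm = config$min_cm, max_cm = config$max_cm,
                              evidence_threshold = config$evidence_p,
                              n_null = config$n_null,
                              generation_time = config$generation_time,
                              reference_year = config$reference_year,
                              seed = config$seed + 6L)
    utils::write.table(format_num_df(ev$curves$tbl),
                       file.path(d, "curves.tsv"),
                       quote = FALSE, row.names = FALSE, sep = "\t")
    ci <- bootstrap_event_ci(ev$curves, n_boot = config$n_boot_date,
                             generation_time = config$generation_time,
                             reference_year = config$reference_year,
                             seed = config$seed + 7L)
    summ <- tibble::tibble(
      detected = ev$detected, p_evidence = ev$p_evidence, g = ev$g,
      year = ev$year, proportion = ev$proportion,
      g_lo = ci$g_lo, g_hi = ci$g_hi, year_lo = ci$year_lo,
      year_hi = ci$year_hi)
    utils::write.table(format_num_df(summ), file.path(d, "event.tsv"),
                       quote = FALSE, row.names = FALSE, sep = "\t")
    if (!is.null(ev$minor_profile)) {
      comp <- tibble::tibble(group = names(ev$minor_profile),
                             minor = as.numeric(ev$minor_profile),
                             major = as.numeric(ev$major_profile))
      utils::write.table(format_num_df(comp), file.path(d, "sources.tsv"),
                         quote = FALSE, row.names = FALSE, sep = "\t")
    }
    res$event <- ev; res$event_ci <- ci
  })

  invisible(res)
}
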