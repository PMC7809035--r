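PIPELINE_STAGES <- c("preprocess", "signatures", "association", "network",
                     "mediation", "morphology", "snrna")

#' Pipeline configuration
#'
#' One validated configuration drives [run_pipeline()]. Exactly one of
#' `synthetic` (arguments for [synthetic_truth()]) or `inputs` (paths to
#' real expression/module/phenotype tables) must be given. Every
#' analysis threshold surfaces as a named parameter with its standard
#' default: fourfold signature rule, FPKM > 1 expression floor, 50 kb GWAS
#' window, alpha 0.05, Bonferroni over the module catalog, BH for the
#' association grid, tenfold cross-validation repeated ten times for the
#' network penalty.
#'
#' @param synthetic list of arguments for [synthetic_truth()] (may be
#'   empty for defaults), or NULL when `inputs` is used.
#' @param inputs list with paths `expression_tsv`, `modules_tsv`,
#'   `phenotypes_csv`, or NULL when `synthetic` is used.
#' @param stages stages to run, in dependency order.
#' @param outdir output directory (created on run).
#' @param seed root seed; all stage randomness derives from it.
#' @param params named overrides of the analysis parameters.
#' @return A validated `mglia_config` list.
#' @export
pipeline_config <- function(synthetic = list(), inputs = NULL,
                            stages = PIPELINE_STAGES,
                            outdir = tempfile("mglianet_run_"),
                            seed = 1L, params = list()) {
  if (!xor(is.null(synthetic), is.null(inputs))) {
    stop("exactly one of `synthetic` or `inputs` must be supplied", call. = FALSE)
  }
  if (length(stages) == 0L) stop("no stage enabled", call. = FALSE)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(inputs)) {
    need <- c("expression_tsv", "modules_tsv", "phenotypes_csv")
    if (!all(need %in% names(inputs))) {
      stop("`inputs` needs expression_tsv, modules_tsv, phenotypes_csv", call. = FALSE)
    }
    missing <- !vapply(inputs[need], file.exists, logical(1))
    if (any(missing)) {
      stop(sprintf("input path(s) not found: %s",
                   paste(unlist(inputs[need])[missing], collapse = ", ")),
           call. = FALSE)
    }
    if (any(c("morphology", "snrna") %in% stages)) {
      stop("morphology/snrna stages require synthetic mode in this build",
           call. = FALSE)
    }
  }
  defaults <- list(fold = 4, min_expr = 1, window = 50000, alpha = 0.05,
                   positive_fraction = 0.10, folds = 10L, repeats = 10L,
                   n_subjects_synth = 200L, cells_per_subject = 60L,
                   image_subjects = 6L, image_effect = -0.3,
                   sn_cells_per_subject = 100L,
                   traits = c("amyloid_sqrt", "tau_sqrt", "decline_slope",
                              "np", "nft", "dp"))
  params <- modifyList(defaults, params)
  structure(list(synthetic = synthetic, inputs = inputs,
                 stages = intersect(PIPELINE_STAGES, stages),
                 outdir = outdir, seed = as.integer(seed), params = params),
            class = "mglia_config")
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order (preprocess ->
#' signatures -> association -> network -> mediation; morphology and
#' snrna are independent), writes tidy CSV outputs, an edge list, and a
#' JSON run summary into the output directory, and returns the result
#' bundle invisibly. Outputs are reproducible from config plus seed
#' alone; a stage failure leaves earlier outputs in place.
#'
#' @param config a [pipeline_config()].
#' @return (Invisibly) a named list of stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mglia_config"))
  p <- config$params
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  log_lines <- c(sprintf("mglianet %s", as.character(utils::packageVersion("mglianet"))),
                 sprintf("seed %d", config$seed),
                 sprintf("stages: %s", paste(config$stages, collapse = ", ")))

  if (!is.null(config$synthetic)) {
    targs <- modifyList(list(n_subjects = p$n_subjects_synth, seed = config$seed),
                        config$synthetic)
    truth <- do.call(synthetic_truth, targs)
    cohort <- generate_cohort(truth)
    expr <- cohort$expression
    modules <- cohort$modules
    phen <- cohort$phenotypes
    res$truth <- truth
  } else {
    expr <- read_expression_tsv(config$inputs$expression_tsv)
    modules <- read_modules_tsv(config$inputs$modules_tsv)
    phen <- readr::read_csv(config$inputs$phenotypes_csv, show_col_types = FALSE)
    truth <- NULL
  }

  if ("preprocess" %in% config$stages) {
    # technical covariates only: age and sex stay in the association models,
    # so their effects on module activity remain visible downstream
    filtered <- filter_genes(quantile_normalize(expr), p$min_expr)
    resid <- residualize(log2_fpkm(filtered),
                         phen[, c("study", "rin", "pmi"), drop = FALSE])
    scores <- module_scores(resid, modules)
    readr::write_csv(scores, file.path(config$outdir, "module_scores.csv"))
    res$preprocess <- list(filtered = filtered, residual = resid,
                           scores = scores)
    log_lines <- c(log_lines,
                   sprintf("preprocess: %d/%d genes kept (mean FPKM > %g)",
                           nrow(filtered), nrow(expr), p$min_expr))
  }

  if ("signatures" %in% config$stages) {
    background <- rownames(res$preprocess$filtered %||% expr)
    if (!is.null(truth)) {
      profiles <- generate_reference_profiles(truth)
      mic <- derive_enriched_set(rowMeans(profiles$microglia),
                                 list(rowMeans(profiles$bulk)),
                                 fold = p$fold, min_expr = p$min_expr,
                                 name = "microglia_signature")
    } else {
      stop("signatures stage requires reference profiles (synthetic mode)",
           call. = FALSE)
    }
    enr <- enrich_modules(modules, mic, background, alpha = p$alpha)
    readr::write_csv(enr, file.path(config$outdir, "module_enrichment.csv"))
    res$signatures <- list(signature = mic, enrichment = enr)
    log_lines <- c(log_lines,
                   sprintf("signatures: %d signature genes, %d enriched module(s)",
                           length(mic$genes), sum(enr$significant)))
  }

  if ("association" %in% config$stages) {
    scores <- res$preprocess$scores
    if (is.null(scores)) stop("association stage needs preprocess", call. = FALSE)
    grid <- associate_modules(scores, phen, traits = p$traits)
    adj <- adjust_multiplicity(grid$p, "bh", alpha = p$alpha)
    grid$significant_bh <- adj$reject
    readr::write_csv(grid, file.path(config$outdir, "module_trait_associations.csv"))
    res$association <- list(grid = grid, bh_threshold = adj$threshold)
    log_lines <- c(log_lines,
                   sprintf("association: %d of %d tests pass BH (threshold %.4g)",
                           sum(adj$reject), nrow(grid),
                           adj$threshold %||% NA_real_))
  }

  if ("network" %in% config$stages) {
    scores <- res$preprocess$scores
    if (is.null(scores)) stop("network stage needs preprocess", call. = FALSE)
    micro <- intersect(c("m5", "m113", "m114", "m115", "m116"), names(scores))
    net <- with_stream(config$seed, "network_cv",
      build_network(scores[, c("sample_id", micro)], phen,
                    traits = c("amyloid_sqrt", "tau_sqrt", "decline_slope",
                               "sex", "age_death"),
                    folds = p$folds, repeats = p$repeats))
    write_network(net, file.path(config$outdir, "network_edges.csv"))
    res$network <- net
    log_lines <- c(log_lines,
                   sprintf("network: lambda %.4g, %d edges among %d visible nodes",
                           net$lambda, nrow(net$edges), length(net$visible)))
  }

  if ("mediation" %in% config$stages) {
    scores <- res$preprocess$scores
    if (is.null(scores)) stop("mediation stage needs preprocess", call. = FALSE)
    dat <- dplyr::inner_join(phen, scores, by = c(subject_id = "sample_id"))
    covs <- dat[, c("rin", "pmi"), drop = FALSE]
    med <- dplyr::bind_rows(
      order_triple(dat$m5, dat$decline_slope, dat$tau_sqrt, covariates = covs,
                   alpha = p$alpha, labels = c("m5", "cogdec", "tau")),
      order_triple(dat$m114, dat$decline_slope, dat$amyloid_sqrt,
                   covariates = covs, alpha = p$alpha,
                   labels = c("m114", "cogdec", "amyloid")))
    readr::write_csv(med, file.path(config$outdir, "mediation_orderings.csv"))
    res$mediation <- med
    log_lines <- c(log_lines,
                   sprintf("mediation: %d supported ordering(s)", sum(med$supported)))
  }

  if ("morphology" %in% config$stages) {
    img <- generate_cell_images(truth, cells_per_subject = p$cells_per_subject,
                                n_subjects = p$image_subjects,
                                effect = p$image_effect)
    cells <- purrr::imap_dfr(img$masks, function(mask, sid) {
      ch <- img$channels[[sid]]
      seg <- segment_cells(mask)
      seg <- call_positivity(seg, ch$pan, "pan", p$positive_fraction)
      seg <- call_positivity(seg, ch$marker, "marker", p$positive_fraction)
      dplyr::mutate(seg, subject_id = sid)
    })
    cmp <- compare_compactness(cells[cells$positive_pan, ], "positive_marker")
    frac <- cells |>
      dplyr::filter(.data$positive_pan) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(fraction = mean(.data$positive_marker)) |>
      dplyr::inner_join(img$subjects, by = "subject_id")
    stage <- positivity_vs_stage(frac$fraction, frac$braak)
    readr::write_csv(dplyr::select(cells, -"pixels"),
                     file.path(config$outdir, "cells.csv"))
    readr::write_csv(frac, file.path(config$outdir, "cells_by_subject.csv"))
    res$morphology <- list(cells = cells, compactness_model = cmp,
                           stage_model = stage)
    log_lines <- c(log_lines,
                   sprintf("morphology: group beta %.3g (p %.3g) over %d cells",
                           cmp$beta, cmp$p, cmp$n_cells))
  }

  if ("snrna" %in% config$stages) {
    sn <- generate_sn_counts(truth,
                             cells = p$sn_cells_per_subject * truth$n_subjects)
    cp <- cpm(sn$counts)
    score5 <- cell_module_score(cp, module_assignment(
      purrr::map_dfr(names(truth$module_defs), function(k) {
        tibble(gene = truth$module_defs[[k]]$genes, module = k)
      })), "m5")
    props <- cluster_proportions(sn$meta)
    assoc <- proportion_trait_assoc(props, "Mic1", sn$phenotypes)
    readr::write_csv(props, file.path(config$outdir, "cluster_proportions.csv"))
    res$snrna <- list(m5_scores = score5, proportions = props,
                      association = assoc, meta = sn$meta)
    log_lines <- c(log_lines,
                   sprintf("snrna: Mic1 proportion vs tau beta %.3g (p %.3g)",
                           assoc$beta, assoc$p))
  }

  summary_list <- list(
    seed = config$seed, stages = config$stages,
    n_subjects = nrow(phen),
    enriched_modules = if (!is.null(res$signatures))
      res$signatures$enrichment$module[res$signatures$enrichment$significant],
    network_edges = if (!is.null(res$network)) nrow(res$network$edges),
    supported_orderings = if (!is.null(res$mediation))
      sum(res$mediation$supported))
  jsonlite::write_json(summary_list, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  invisible(res)
}
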