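#' Build a pipeline configuration
#'
#' One structured list of stage toggles and stage parameters driving
#' [run_pipeline()]. A single `seed` fans out to per-stage seeds by fixed
#' offsets (bulk simulation `seed`, cell simulation `seed + 1000`, clonotype
#' simulation `seed + 2000`, gene-set control sampling `seed + 3000`), so
#' one knob reproduces the whole run. The configuration round-trips through
#' YAML unchanged ([write_config()] / [read_config()]).
#'
#' @param seed Master integer seed.
#' @param stages Named logical list toggling `simulate`, `preprocess`,
#'   `agelm`, `trajectory`, `deswan`, `single_cell`, `repertoire`.
#' @param inputs Optional list with `expr`/`meta` TSV paths used instead of
#'   simulation when the simulate stage is off.
#' @param simulate,preprocess,agelm,trajectory,deswan,single_cell,repertoire
#'   Named lists overriding individual stage parameters (see the default
#'   values in the function definition).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, stages = list(), inputs = list(),
                            simulate = list(), preprocess = list(),
                            agelm = list(), trajectory = list(),
                            deswan = list(), single_cell = list(),
                            repertoire = list()) {
  merge_over <- function(defaults, user) {
    stopifnot(all(names(user) %in% names(defaults)))
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    seed = as.numeric(seed),
    stages = merge_over(list(
      simulate = TRUE, preprocess = TRUE, agelm = TRUE, trajectory = TRUE,
      deswan = TRUE, single_cell = TRUE, repertoire = TRUE
    ), stages),
    inputs = merge_over(list(expr = NULL, meta = NULL), inputs),
    simulate = merge_over(list(
      n_samples = 120, age_range = c(1, 99),
      n_flat = 150, n_linear = 60, n_saturating = 45, n_transient = 45,
      slope = 0.02, change_age = 40, half_width = 8, amplitude = 1,
      noise_sd = 0.5, batch_offsets = c(0, 1), batch_scales = c(1, 1.2)
    ), simulate),
    preprocess = merge_over(list(
      min_fraction = 0.75, covariates = "~ age + sex", filter_first = TRUE
    ), preprocess),
    agelm = merge_over(list(q_cut = 0.05, beta_cut = 0.005), agelm),
    trajectory = merge_over(list(
      span = 0.75, degree = 2, k = 6, k_range = c(6, 12),
      linkage = "complete"
    ), trajectory),
    deswan = merge_over(list(
      centers = 10:90, half_width = 10,
      q_cutoffs = c(0.001, 0.01, 0.05), crest_smooth = 3,
      top_q_cut = 0.01, top_beta_cut = 0.5
    ), deswan),
    single_cell = merge_over(list(
      n_cells = 300, cell_types = c("Mono", "T", "B"), n_genes = 120,
      n_marker_genes = 10, marker_shift = 2, n_bins = 10, ctrl_size = 20,
      sample_ages = c(d1 = 8, d2 = 30, d3 = 50, d4 = 65, d5 = 80, d6 = 90)
    ), single_cell),
    repertoire = merge_over(list(
      n_cells = c(d1 = 150, d2 = 150, d3 = 150, d4 = 150),
      ages = c(d1 = 30, d2 = 50, d3 = 70, d4 = 85),
      clone_dist = "geometric", rate = c(0.9, 0.9, 0.5, 0.35)
    ), repertoire)
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      preprocess$min_fraction > 0, preprocess$min_fraction <= 1,
      trajectory$span > 0, trajectory$span <= 1,
      trajectory$k >= trajectory$k_range[1],
      trajectory$k <= trajectory$k_range[2],
      deswan$half_width > 0,
      all(deswan$q_cutoffs > 0 & deswan$q_cutoffs < 1),
      simulate$noise_sd >= 0,
      all(simulate$batch_scales > 0),
      single_cell$n_bins >= 2
    )
  })
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  on <- names(Filter(isTRUE, x$stages))
  cat("pipeline_config (seed", x$seed, ")\n  stages:",
      paste(on, collapse = " "), "\n")
  invisible(x)
}

#' Serialize / load a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` invisibly returns `path`; `read_config` returns
#'   the `pipeline_config`.
#' @export
write_config <- function(config, path) {
  # serialize named atomic vectors as maps so their names survive YAML
  namify <- function(x) {
    if (is.list(x)) return(lapply(x, namify))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  yaml::write_yaml(namify(unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("single_cell", "repertoire")) {
    for (field in c("sample_ages", "n_cells", "ages")) {
      if (!is.null(cfg[[nm]][[field]])) {
        cfg[[nm]][[field]] <- unlist(cfg[[nm]][[field]])
      }
    }
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

.flatten_config <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x[[nm]])) {
      out <- c(out, .flatten_config(x[[nm]], key))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or load inputs),
#' preprocess (prevalence filter then batch adjustment), per-gene age linear
#' model, LOESS trajectory clustering, DE-SWAN scan, single-cell statistics
#' (simulated cells: gene-set scoring, rank-sum DE, proportion/age
#' correlation), and TCR repertoire indices — writing every table as TSV
#' into `outdir` together with `config.yaml`, a `manifest.tsv` declaring
#' every output file with its stage and row count, and `run.log` listing the
#' parameters that deviate from the defaults. Reruns with an identical
#' configuration are bit-identical.
#'
#' Disabled dependencies are errors: e.g. the DE-SWAN stage without the
#' preprocess stage aborts naming `preprocess`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  manifest <- list()
  results <- list()
  declare <- function(path, stage, rows) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      file = basename(path), stage = stage, rows = rows,
      stringsAsFactors = FALSE)
    path
  }

  # deviations from defaults -> run.log
  defaults <- .flatten_config(unclass(pipeline_config(seed = config$seed)))
  current <- .flatten_config(unclass(config))
  dev <- Filter(function(nm) !identical(current[[nm]], defaults[[nm]]),
                names(current))
  writeLines(c(
    paste("pipeline seed:", config$seed),
    if (length(dev)) {
      vapply(dev, function(nm) {
        paste0("param ", nm, " = ", paste(format(current[[nm]]),
                                          collapse = ","))
      }, character(1))
    } else "all parameters at defaults"
  ), file.path(outdir, "run.log"))

  cohort <- NULL
  if (isTRUE(st$simulate)) {
    sc <- config$simulate
    arch <- archetype_table(
      sc$n_flat + sc$n_linear + sc$n_saturating + sc$n_transient,
      kind = rep(c("flat", "linear", "saturating", "transient"),
                 times = c(sc$n_flat, sc$n_linear, sc$n_saturating,
                           sc$n_transient)),
      slope = sc$slope, change_age = sc$change_age,
      half_width = sc$half_width, amplitude = sc$amplitude)
    cohort <- simulate_cohort(sc$n_samples, sc$age_range, arch,
                              batch_offsets = sc$batch_offsets,
                              batch_scales = sc$batch_scales,
                              noise_sd = sc$noise_sd, seed = config$seed)
    write_cohort(cohort, file.path(outdir, "expression.tsv"),
                 file.path(outdir, "samples.tsv"),
                 file.path(outdir, "truth.yaml"))
    declare(file.path(outdir, "expression.tsv"), "simulate",
            nrow(cohort$expr))
    declare(file.path(outdir, "samples.tsv"), "simulate",
            nrow(cohort$samples))
    declare(file.path(outdir, "truth.yaml"), "simulate",
            nrow(cohort$truth$archetypes))
    results$cohort <- cohort
  } else if (!is.null(config$inputs$expr)) {
    cohort <- read_cohort(config$inputs$expr, config$inputs$meta)
    results$cohort <- cohort
  }

  need_cohort <- function(stage) {
    if (is.null(cohort)) {
      stop("stage '", stage, "' requires the 'simulate' stage ",
           "or input expression/metadata paths")
    }
  }
  processed <- NULL
  if (isTRUE(st$preprocess)) {
    need_cohort("preprocess")
    pp <- config$preprocess
    filtered <- filter_genes(cohort, pp$min_fraction)
    processed <- combat_adjust(filtered,
                               covariates = stats::as.formula(pp$covariates))
    qc <- batch_qc(filtered, processed)
    write.table(qc$medians, file.path(outdir, "batch_qc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    declare(file.path(outdir, "batch_qc.tsv"), "preprocess",
            nrow(qc$medians))
    processed_out <- processed
    processed_out$truth <- NULL   # ground truth already written by simulate
    write_cohort(processed_out, file.path(outdir, "expression_adjusted.tsv"),
                 file.path(outdir, "samples_adjusted.tsv"))
    declare(file.path(outdir, "expression_adjusted.tsv"), "preprocess",
            nrow(processed$expr))
    declare(file.path(outdir, "samples_adjusted.tsv"), "preprocess",
            nrow(processed$samples))
    results$processed <- processed
    results$batch_qc <- qc
  }
  need_processed <- function(stage) {
    if (is.null(processed)) {
      stop("stage '", stage, "' requires the 'preprocess' stage")
    }
  }

  if (isTRUE(st$agelm)) {
    need_processed("agelm")
    fit <- fit_age_lm(processed)
    write_age_lm(fit, file.path(outdir, "age_lm.tsv"),
                 q_cut = config$agelm$q_cut, beta_cut = config$agelm$beta_cut)
    declare(file.path(outdir, "age_lm.tsv"), "agelm", nrow(fit$table))
    results$age_lm <- fit
  }

  if (isTRUE(st$trajectory)) {
    need_processed("trajectory")
    tj <- config$trajectory
    atlas <- fit_trajectories(processed, span = tj$span, degree = tj$degree)
    atlas <- cluster_trajectories(atlas, k = tj$k, k_range = tj$k_range,
                                  linkage = tj$linkage)
    write_trajectories(atlas, file.path(outdir, "trajectories.tsv"),
                       file.path(outdir, "trajectory_clusters.tsv"),
                       file.path(outdir, "trajectory_cluster_means.tsv"))
    declare(file.path(outdir, "trajectories.tsv"), "trajectory",
            nrow(atlas$pred))
    declare(file.path(outdir, "trajectory_clusters.tsv"), "trajectory",
            length(atlas$cluster))
    declare(file.path(outdir, "trajectory_cluster_means.tsv"), "trajectory",
            nrow(atlas$cluster_means))
    results$atlas <- atlas
  }

  if (isTRUE(st$deswan)) {
    need_processed("deswan")
    dw <- config$deswan
    profile <- deswan_scan(processed, centers = dw$centers,
                           half_width = dw$half_width,
                           q_cutoffs = dw$q_cutoffs,
                           crest_smooth = dw$crest_smooth)
    write_deswan(profile, file.path(outdir, "deswan_counts.tsv"),
                 file.path(outdir, "deswan_stats.tsv"),
                 file.path(outdir, "deswan_crests.tsv"))
    declare(file.path(outdir, "deswan_counts.tsv"), "deswan",
            nrow(profile$counts))
    declare(file.path(outdir, "deswan_stats.tsv"), "deswan",
            nrow(profile$beta) * length(profile$centers))
    declare(file.path(outdir, "deswan_crests.tsv"), "deswan",
            length(profile$crests))
    td <- top_degs(profile, q_cut = dw$top_q_cut, beta_cut = dw$top_beta_cut)
    write.table(td, file.path(outdir, "deswan_top_degs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    declare(file.path(outdir, "deswan_top_degs.tsv"), "deswan", nrow(td))
    results$deswan <- profile
  }

  if (isTRUE(st$single_cell)) {
    sc <- config$single_cell
    markers <- data.frame(
      type = sc$cell_types[1],
      gene = sprintf("g%03d", seq_len(sc$n_marker_genes)),
      shift = sc$marker_shift, stringsAsFactors = FALSE)
    cells <- simulate_single_cell(sc$n_cells, sc$cell_types,
                                  markers = markers, n_genes = sc$n_genes,
                                  sample_ages = sc$sample_ages,
                                  seed = config$seed + 1000)
    score <- score_gene_set(cells, gene_set = markers$gene,
                            n_bins = sc$n_bins, ctrl_size = sc$ctrl_size,
                            seed = config$seed + 3000)
    write.table(data.frame(cell = names(score), score = as.numeric(score)),
                file.path(outdir, "cell_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    declare(file.path(outdir, "cell_scores.tsv"), "single_cell",
            length(score))
    de <- rank_sum_de(cells, cells$cells$type == sc$cell_types[1],
                      cells$cells$type == sc$cell_types[2])
    write.table(de, file.path(outdir, "cell_de.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    declare(file.path(outdir, "cell_de.tsv"), "single_cell", nrow(de))
    pa <- proportion_age_correlation(cells)
    props_long <- data.frame(
      sample = rep(rownames(pa$props), ncol(pa$props)),
      type = rep(colnames(pa$props), each = nrow(pa$props)),
      fraction = as.vector(pa$props),
      age = rep(pa$ages, ncol(pa$props)))
    write.table(props_long, file.path(outdir, "cell_proportions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    declare(file.path(outdir, "cell_proportions.tsv"), "single_cell",
            nrow(props_long))
    results$cells <- cells
    results$score <- score
    results$cell_de <- de
    results$proportions <- pa
  }

  if (isTRUE(st$repertoire)) {
    rp <- config$repertoire
    truth <- clonotype_truth(rp$n_cells, ages = rp$ages,
                             clone_dist = rp$clone_dist, rate = rp$rate,
                             seed = config$seed + 2000)
    tab <- simulate_clonotypes(truth)
    write.table(tab, file.path(outdir, "clonotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    declare(file.path(outdir, "clonotypes.tsv"), "repertoire", nrow(tab))
    rep_sum <- repertoire_by_group(tab)
    write.table(rep_sum$indices, file.path(outdir, "repertoire_indices.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    declare(file.path(outdir, "repertoire_indices.tsv"), "repertoire",
            nrow(rep_sum$indices))
    results$repertoire <- rep_sum
  }

  write_config(config, file.path(outdir, "config.yaml"))
  declare(file.path(outdir, "config.yaml"), "config", 1L)
  manifest_df <- do.call(rbind, manifest)
  write.table(manifest_df, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  results$manifest <- manifest_df
  invisible(results)
}
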