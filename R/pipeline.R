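#' Pipeline configuration
#'
#' Collects the knobs of [run_full_analysis()]. Either file paths
#' (`matrix_path`, `trees_path`, `metadata_path`) or in-memory objects
#' (`matrix`, `trees`, `metadata`) can be supplied. `pipeline_config()`
#' validates and fills defaults; `read_pipeline_config()` loads the same
#' fields from a YAML file.
#'
#' @param matrix_path,trees_path,metadata_path input file paths.
#' @param matrix,trees,metadata in-memory inputs (a [clado_matrix()], a
#'   `multiPhylo`/list of `phylo`, a metadata data.frame).
#' @param exclusions named list of taxon-name vectors: `non_ingroup`,
#'   `suprageneric` (dropped before every analysis), `outliers` and
#'   `uncertain` (used for sensitivity reruns; `uncertain` taxa are also
#'   excluded from the PERMANOVA).
#' @param bins a [bin_table()].
#' @param axes_disparity,axes_regression number of ordination axes retained
#'   for the disparity metrics (study-style default 17) and regressions
#'   (default 3); capped at the number of positive axes.
#' @param n_boot,n_perm,iterations bootstrap replicates (odd), PERMANOVA
#'   permutations, RRPP iterations.
#' @param rarefy_to rarefaction size for the rarefied intervals (default 7);
#'   groups smaller than this skip rarefaction.
#' @param partition optional named list: region -> 1-based character
#'   indices, for partitioned WMPD.
#' @param models list of regression formulas (strings); default a small
#'   body-mass/continent suite.
#' @param trees_sample number of trees drawn for the regression suite
#'   (default 10).
#' @param mbl minimum branch duration (Myr) for time calibration.
#' @param seed master seed.
#' @param out_dir optional output directory for [write_results()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, trees_path = NULL,
                            metadata_path = NULL,
                            matrix = NULL, trees = NULL, metadata = NULL,
                            exclusions = list(),
                            bins = default_bin_table(),
                            axes_disparity = 17, axes_regression = 3,
                            n_boot = 9999, n_perm = 9999, iterations = 999,
                            rarefy_to = 7,
                            partition = NULL,
                            models = list("~ log_body_mass", "~ continent",
                                          "~ log_body_mass + continent"),
                            trees_sample = 10, mbl = 0.1,
                            seed = 1234, out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$axes_disparity >= 1, cfg$axes_regression >= 1,
            cfg$n_boot > 0, cfg$n_perm > 0, cfg$iterations > 0)
  for (p in c("matrix_path", "trees_path", "metadata_path")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("configured file does not exist: ", cfg[[p]])
    }
  }
  if (is.null(cfg$matrix) && is.null(cfg$matrix_path)) {
    stop("either `matrix` or `matrix_path` is required")
  }
  known <- c("non_ingroup", "suprageneric", "outliers", "uncertain")
  unknown <- setdiff(names(cfg$exclusions), known)
  if (length(unknown)) stop("unknown exclusion class: ",
                            paste(unknown, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @describeIn pipeline_config read a config from YAML. Recognized keys
#'   mirror the arguments; `bins` is a list of `{label, older, younger}`
#'   records and `partition` maps region names to index vectors.
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$bins)) {
    y$bins <- bin_table(vapply(y$bins, `[[`, "", "label"),
                        vapply(y$bins, function(b) as.numeric(b$older), 0),
                        vapply(y$bins, function(b) as.numeric(b$younger), 0))
  }
  if (!is.null(y$partition)) y$partition <- lapply(y$partition, as.integer)
  do.call(pipeline_config, y)
}

bin_groups_from_metadata <- function(metadata, taxa) {
  labs <- unique(unlist(metadata$bins))
  out <- lapply(stats::setNames(labs, labs), function(b) {
    intersect(metadata$taxon[vapply(metadata$bins, function(x) b %in% x,
                                    TRUE)], taxa)
  })
  out[lengths(out) >= 2]
}

#' Run the full disparity and regression workflow
#'
#' Executes, in order: input reading and exclusions; MORD distances; WMPD
#' (per time bin, locomotion class, full sample -- each with bootstrap CIs,
#' and recomputed without the ordination-trimmed taxa); trimming; PCoA with
#' Lingoes correction and axis selection; SoV, SoR and centroid
#' displacements per bin with bootstrap and rarefied CIs; sensitivity reruns
#' pruning flagged outlier/uncertain taxa; PERMANOVA between bins;
#' partitioned WMPD per anatomical region (when a partition is configured);
#' minimum-branch-length calibration of the trees; Fitch imputation of
#' missing locomotion states; Brownian-motion ancestral log body mass; and
#' the regression model suite. Stage failures are re-signalled with the
#' stage name; everything is deterministic given the config seed.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @return list of class `pipeline_result` with elements `matrix`,
#'   `metadata`, `dist`, `wmpd` (data.frame), `trim`, `ordination`,
#'   `k_disparity`, `cumulative_variance`, `disparity` (data.frame of all
#'   estimates), `permanova`, `partition_wmpd`, `calibrated_trees`,
#'   `locomotion_imputed`, `mass_ancestral`, `regressions`, `bias_test`,
#'   `log`, `files` (when `out_dir` is set).
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  t0 <- proc.time()[3]
  note <- function(...) {
    msg <- sprintf("[%7.2fs] %s", proc.time()[3] - t0, paste0(...))
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  note("seed = ", config$seed, "; cladospace ",
       as.character(utils::packageVersion("cladospace")))

  ## --- read + exclude ---------------------------------------------------
  mat <- stage("read_matrix",
    config$matrix %||% read_character_matrix(config$matrix_path))
  meta <- stage("read_metadata", {
    m <- config$metadata %||%
      (if (!is.null(config$metadata_path))
         read_taxon_metadata(config$metadata_path, config$bins))
    if (is.null(m)) stop("metadata required")
    m
  })
  trees <- stage("read_trees", {
    tr <- config$trees %||%
      (if (!is.null(config$trees_path))
         read_tree_file(config$trees_path, matrix_taxa = mat$taxa))
    if (inherits(tr, "phylo")) tr <- list(tr)
    tr
  })
  drop <- unique(c(config$exclusions$non_ingroup,
                   config$exclusions$suprageneric))
  keep <- setdiff(mat$taxa, drop)
  mat <- cm_subset(mat, taxa = keep)
  meta <- meta[meta$taxon %in% keep, , drop = FALSE]
  note("terminals after exclusions: ", length(mat$taxa))

  ## --- distances + WMPD --------------------------------------------------
  dist <- stage("mord", mord_matrix(mat))
  trim <- stage("trim", trim_for_ordination(dist, mat))
  note("taxa trimmed before ordination: ", length(trim$removed),
       if (length(trim$removed))
         paste0(" (", paste(trim$removed, collapse = ", "), ")") else "")

  groups_bins <- bin_groups_from_metadata(meta, mat$taxa)
  groups_loco <- split(meta$taxon, meta$locomotion)
  groups_loco <- groups_loco[setdiff(names(groups_loco), "unknown")]
  groups_loco <- lapply(groups_loco, intersect, y = mat$taxa)
  groups_loco <- groups_loco[lengths(groups_loco) >= 2]

  wmpd_rows <- list()
  add_wmpd <- function(label, group, suffix = "") {
    est <- bootstrap_ci(dist, group, "WMPD", n_boot = config$n_boot,
                        seed = config$seed)
    wmpd_rows[[length(wmpd_rows) + 1L]] <<- data.frame(
      bin = label, metric = paste0("WMPD", suffix), value = est$value,
      lower = est$ci_lower, upper = est$ci_upper,
      n_taxa = est$n_taxa, stringsAsFactors = FALSE)
  }
  stage("wmpd", {
    add_wmpd("all", mat$taxa)
    for (b in names(groups_bins)) add_wmpd(b, groups_bins[[b]])
    for (l in names(groups_loco)) add_wmpd(l, groups_loco[[l]])
    # recomputed without the taxa trimmed for ordination
    if (length(trim$removed)) {
      for (b in names(groups_bins)) {
        g <- setdiff(groups_bins[[b]], trim$removed)
        if (length(g) >= 2) add_wmpd(b, g, suffix = "_untrimmed_removed")
      }
    }
  })
  wmpd_tab <- do.call(rbind, wmpd_rows)

  ## --- ordination ---------------------------------------------------------
  ord <- stage("pcoa", {
    o <- pcoa_lingoes(trim$dist)
    o$trimmed_taxa <- trim$removed
    o
  })
  k <- min(config$axes_disparity, ncol(ord$coordinates))
  cumvar <- axis_variance(ord, k)
  note("retained ", k, " axes (", sprintf("%.2f", cumvar),
       "% cumulative variance); Lingoes c = ",
       format(ord$lingoes_constant, digits = 4))
  coords <- ord$coordinates[, seq_len(k), drop = FALSE]

  bias <- stage("missing_bias",
    tryCatch(missing_data_bias_test(coords, mat), error = function(e) NULL))

  ## --- post-ordination disparity ------------------------------------------
  ord_bins <- lapply(groups_bins, intersect, y = ord$taxa)
  ord_bins <- ord_bins[lengths(ord_bins) >= 2]
  bin_order <- config$bins$label[config$bins$label %in% names(ord_bins)]
  bin_order <- c(bin_order, setdiff(names(ord_bins), bin_order))
  disp_rows <- list()
  add_disp <- function(label, est, reference = NA_character_) {
    disp_rows[[length(disp_rows) + 1L]] <<- data.frame(
      bin = label, metric = est$metric, reference = reference,
      value = est$value, lower = est$ci_lower, upper = est$ci_upper,
      n_taxa = est$n_taxa,
      rarefied_to = if (is.null(est$rarefied_to)) NA else est$rarefied_to,
      stringsAsFactors = FALSE)
  }
  stage("disparity_metrics", {
    prev_centroid <- NULL
    for (b in bin_order) {
      g <- ord_bins[[b]]
      for (metric in c("SoV", "SoR")) {
        add_disp(b, bootstrap_ci(coords, g, metric, n_boot = config$n_boot,
                                 seed = config$seed))
        if (!is.null(config$rarefy_to) && config$rarefy_to <= length(g)) {
          add_disp(b, bootstrap_ci(coords, g, metric, n_boot = config$n_boot,
                                   rarefy_to = config$rarefy_to,
                                   seed = config$seed))
        }
      }
      add_disp(b, bootstrap_ci(coords, g, "displacement",
                               n_boot = config$n_boot, seed = config$seed,
                               reference = "global-centroid"),
               reference = "global-centroid")
      est_prev <- if (is.null(prev_centroid)) {
        bootstrap_ci(coords, g, "displacement", n_boot = config$n_boot,
                     seed = config$seed, reference = "own-centroid")
      } else {
        bootstrap_ci(coords, g, "displacement", n_boot = config$n_boot,
                     seed = config$seed, reference = "given",
                     reference_centroid = prev_centroid)
      }
      add_disp(b, est_prev, reference = "previous-bin-centroid")
      prev_centroid <- colMeans(coords[g, , drop = FALSE])
    }
    for (l in names(groups_loco)) {
      g <- intersect(groups_loco[[l]], ord$taxa)
      if (length(g) < 2) next
      for (metric in c("SoV", "SoR")) {
        add_disp(l, bootstrap_ci(coords, g, metric, n_boot = config$n_boot,
                                 seed = config$seed))
      }
      add_disp(l, bootstrap_ci(coords, g, "displacement",
                               n_boot = config$n_boot, seed = config$seed,
                               reference = "global-centroid"),
               reference = "global-centroid")
    }
    # sensitivity rerun: prune flagged outliers / chronologically uncertain
    flagged <- intersect(unique(c(config$exclusions$outliers,
                                  config$exclusions$uncertain)), ord$taxa)
    if (length(flagged)) {
      for (b in bin_order) {
        g <- setdiff(ord_bins[[b]], flagged)
        if (length(g) < 2) next
        for (metric in c("SoV", "SoR")) {
          est <- bootstrap_ci(coords, g, metric, n_boot = config$n_boot,
                              seed = config$seed)
          est$metric <- paste0(metric, "_pruned")
          add_disp(b, est)
        }
      }
    }
  })
  disp_tab <- do.call(rbind, disp_rows)

  ## --- PERMANOVA between bins ---------------------------------------------
  perm <- stage("permanova", {
    excl <- config$exclusions$uncertain
    single_bin <- meta$taxon[lengths(meta$bins) == 1]
    lab <- stats::setNames(vapply(meta$bins, `[`, "", 1), meta$taxon)
    lab <- lab[intersect(setdiff(single_bin, excl), ord$taxa)]
    if (length(unique(lab)) >= 2 && all(table(lab) >= 2)) {
      permanova(coords, lab, n_perm = config$n_perm, seed = config$seed)
    } else NULL
  })
  if (!is.null(perm)) {
    note("PERMANOVA: F = ", sprintf("%.4f", perm$F),
         ", R2 = ", sprintf("%.4f", perm$R2), ", p = ", format(perm$p))
  }

  ## --- partitioned WMPD -----------------------------------------------------
  part_tab <- NULL
  if (!is.null(config$partition)) {
    part_tab <- stage("partition_wmpd", {
      parts <- partition_characters(mat, config$partition)
      rows <- list()
      for (r in names(parts)) {
        pd <- mord_matrix(parts[[r]])
        for (b in names(groups_bins)) {
          g <- groups_bins[[b]]
          val <- tryCatch(wmpd(pd, g), error = function(e) NA_real_)
          rows[[length(rows) + 1L]] <- data.frame(
            region = r, bin = b, metric = "WMPD", value = val,
            stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
  }

  ## --- tree work -------------------------------------------------------------
  fads <- stats::setNames(meta$fad_ma, meta$taxon)
  cal_trees <- NULL; loco_imp <- NULL; anc_mass <- NULL; reg <- NULL
  if (length(trees)) {
    cal_trees <- stage("calibrate", lapply(trees, function(tr) {
      tr <- ape::keep.tip(tr, intersect(tr$tip.label, names(fads)))
      calibrate_mbl(tr, fads, mbl = config$mbl)
    }))
    note("calibrated ", length(cal_trees), " tree(s), mbl = ", config$mbl)
    loco <- stats::setNames(meta$locomotion, meta$taxon)
    if (any(loco != "unknown")) {
      loco_imp <- stage("fitch_impute",
        fitch_impute_states(if (length(cal_trees) > 1) cal_trees
                            else cal_trees[[1]],
                            replace(loco, loco == "unknown", NA)))
      imp <- loco_imp$tip_states
      known <- !is.na(imp) & imp != "unknown"
      meta$locomotion[match(names(imp)[known], meta$taxon)] <- imp[known]
      note("locomotion imputed for ",
           sum(loco[names(imp)] %in% "unknown" & known), " taxa (",
           sum(loco_imp$ambiguous), " ambiguous)")
    }
    mass <- stats::setNames(meta$log_body_mass, meta$taxon)
    if (!anyNA(mass)) {
      anc_mass <- stage("bm_ancestral",
        bm_ancestral_states(cal_trees[[1]], mass))
    }
    reg <- stage("regressions", {
      kr <- min(config$axes_regression, ncol(ord$coordinates))
      rc <- ord$coordinates[, seq_len(kr), drop = FALSE]
      md <- meta[meta$taxon %in% rownames(rc), , drop = FALSE]
      rc <- rc[md$taxon, , drop = FALSE]
      model_suite(config$models, rc, md, cal_trees,
                  iterations = config$iterations,
                  trees_sample = config$trees_sample, seed = config$seed)
    })
  }

  ## --- write -------------------------------------------------------------
  all_disp <- rbind(
    cbind(wmpd_tab, reference = NA_character_, rarefied_to = NA)[,
      c("bin", "metric", "reference", "value", "lower", "upper", "n_taxa",
        "rarefied_to")],
    disp_tab)
  files <- NULL
  if (!is.null(config$out_dir)) {
    cfg_txt <- tempfile(); saveRDS(unclass(config)[
      setdiff(names(config), c("matrix", "trees", "metadata"))], cfg_txt)
    note("config hash: ", unname(tools::md5sum(cfg_txt)))
    files <- stage("write_results",
      write_results(all_disp, config$out_dir, coordinates = coords,
                    regressions = reg, log_lines = log_lines))
  }
  structure(list(matrix = mat, metadata = meta, dist = dist,
                 wmpd = wmpd_tab, trim = trim, ordination = ord,
                 k_disparity = k, cumulative_variance = cumvar,
                 disparity = all_disp, permanova = perm,
                 partition_wmpd = part_tab, calibrated_trees = cal_trees,
                 locomotion_imputed = loco_imp, mass_ancestral = anc_mass,
                 regressions = reg, bias_test = bias,
                 log = log_lines, files = files),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(" ", length(x$matrix$taxa), "terminals;",
      length(x$trim$removed), "trimmed;", x$k_disparity, "axes (",
      sprintf("%.2f%%", x$cumulative_variance), "cumulative variance )\n")
  if (!is.null(x$permanova)) {
    cat("  PERMANOVA p =", format(x$permanova$p), "\n")
  }
  cat("  disparity rows:", nrow(x$disparity), "\n")
  invisible(x)
}
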