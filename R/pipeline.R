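#' Default analysis configuration
#'
#' Flat key-value configuration shared by [run_pipeline()] and the
#' command-line front end. Any subset of keys can be overridden; unknown
#' keys are rejected.
#'
#' Keys (dot-named, with defaults): `filter.fc` (10 Hz), `filter.order`
#' (2), `events.k_sigma` (2.5), `events.min_sustain_ms` (50),
#' `pca.threshold` (0.999 cumulative explained variance), `bootstrap.B`
#' (10000), `ellipse.level` (0.95), `jaccard.method` ("membership"),
#' `gmm.K` (2), `gmm.tol` (1e-8), `gmm.max_iter` (500), `gmm.n_init` (10),
#' `gmm.reg_floor` (1e-8), `subspaces` (list of PC index pairs, default
#' PC1/PC2 and PC2/PC3).
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
gi_config <- function(...) {
  defaults <- list(
    filter.fc = 10, filter.order = 2,
    events.k_sigma = 2.5, events.min_sustain_ms = 50,
    pca.threshold = 0.999,
    bootstrap.B = 10000,
    ellipse.level = 0.95,
    jaccard.method = "membership",
    gmm.K = 2, gmm.tol = 1e-8, gmm.max_iter = 500, gmm.n_init = 10,
    gmm.reg_floor = 1e-8,
    subspaces = list(c(1, 2), c(2, 3)))
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    abort("All configuration overrides must be named.")
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, over)
}

#' Run the full gait-initiation classification pipeline
#'
#' Executes the end-to-end method on a cohort: (optionally) extract the 11
#' registry features from raw trials, standardize and fit the PCA, select
#' the number of components by cumulative explained variance, bootstrap the
#' per-group mean scores, measure cluster separation with the Jaccard
#' overlap of the 95\% confidence ellipses, and classify the pooled
#' bootstrapped means with a two-component Gaussian mixture model in each
#' analyzed 2-D subspace (PC1/PC2 and PC2/PC3 by default).
#'
#' A single global `seed` deterministically derives every per-stage random
#' stream (group bootstraps, GMM initializations), so a rerun with the same
#' inputs, configuration and seed reproduces the report exactly.
#'
#' @param data Either a feature table (data frame with `group` plus the 11
#'   registry columns; the direct path) or a list of `gi_trial` objects
#'   (the kinetics path, requiring `groups`).
#' @param groups Group label per trial when `data` is a list of trials.
#' @param config Configuration list from [gi_config()].
#' @param seed Global integer seed.
#' @param out_dir Optional directory to which the report and its CSV/JSON
#'   artifacts are written.
#' @return A `gi_report`: list with the echoed `config` and `seed`, the
#'   feature table used, `pca` model, `k` retained components,
#'   `explained` tibble, `simplified` loading summary, per-subspace
#'   results (`jaccard`, `gmm`, `confusion`, clouds) and the package
#'   version.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(seed = 1))
#' rep <- run_pipeline(cohort, config = gi_config(bootstrap.B = 200,
#'                                                gmm.n_init = 2),
#'                     seed = 1)
#' rep$jaccard
run_pipeline <- function(data, groups = NULL, config = gi_config(),
                         seed = 1, out_dir = NULL) {
  cfg <- utils::modifyList(gi_config(), config)

  features <- if (is.data.frame(data)) {
    as_tibble(data)
  } else if (is.list(data) && all(vapply(data, inherits, logical(1), "gi_trial"))) {
    if (is.null(groups) || length(groups) != length(data)) {
      abort("Kinetics path needs one `groups` label per trial.")
    }
    ft <- purrr::map_dfr(data, function(tr) {
      extract_features(tr, fc = cfg$filter.fc, order = cfg$filter.order,
                       k_sigma = cfg$events.k_sigma,
                       min_sustain_ms = cfg$events.min_sustain_ms)
    })
    dplyr::bind_cols(
      tibble(participant_id = sprintf("P%02d", seq_along(data)),
             group = as.character(groups)),
      ft)
  } else {
    abort("`data` must be a feature table or a list of gi_trial objects.")
  }

  if (!"group" %in% names(features)) {
    abort("Feature table must have a `group` column.")
  }
  check_feature_columns(features, gi_features())

  pca <- fit_pca(features)
  k <- choose_k(pca, cfg$pca.threshold)
  k_use <- max(k, max(unlist(cfg$subspaces)))
  scores <- project(pca, features, k = k_use)

  clouds <- bootstrap_group_means(scores, "group",
                                  cols = paste0("PC", seq_len(k_use)),
                                  B = cfg$bootstrap.B,
                                  seed = derive_seed(seed, "boot_control"))
  if (length(clouds) != 2L) {
    abort("The headline pipeline expects exactly two groups.")
  }

  subspace_results <- purrr::map(cfg$subspaces, function(ss) {
    pcs <- paste0("PC", ss)
    a <- clouds[[1]]$means[pcs]
    b <- clouds[[2]]$means[pcs]
    j <- jaccard_overlap(a, b, level = cfg$ellipse.level,
                         method = cfg$jaccard.method,
                         seed = derive_seed(seed, "jaccard"))
    pooled <- dplyr::bind_rows(
      dplyr::mutate(a, group = clouds[[1]]$group),
      dplyr::mutate(b, group = clouds[[2]]$group))
    gmm <- fit_gmm(pooled, K = cfg$gmm.K, cols = pcs,
                   seed = derive_seed(seed, "gmm") + 13 * ss[1] + ss[2],
                   tol = cfg$gmm.tol, max_iter = cfg$gmm.max_iter,
                   n_init = cfg$gmm.n_init, reg_floor = cfg$gmm.reg_floor)
    cl <- classify(gmm, pooled[pcs])
    conf <- align_and_confuse(pooled$group, cl$cluster)
    list(subspace = paste0("PC", ss[1], "/PC", ss[2]),
         pcs = pcs, jaccard = j, gmm = gmm, confusion = conf)
  })
  names(subspace_results) <- vapply(subspace_results, `[[`, "", "subspace")

  report <- structure(
    list(config = cfg, seed = seed,
         features = features, pca = pca, k = k,
         explained = tibble(component = paste0("PC", seq_along(pca$explained_fraction)),
                            fraction = pca$explained_fraction,
                            cumulative = cumsum(pca$explained_fraction)),
         simplified = simplify_loadings(pca, components = k_use),
         clouds = clouds,
         jaccard = stats::setNames(
           vapply(subspace_results, `[[`, numeric(1), "jaccard"),
           names(subspace_results)),
         subspaces = subspace_results,
         version = as.character(utils::packageVersion("gipca"))),
    class = "gi_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Human-readable loading summary of a fitted PCA
#'
#' Condenses each principal component the way practitioners read them:
#' coefficients with magnitude below `drop_below` are marked dropped, and
#' kept variables whose coefficient magnitudes differ by less than
#' `merge_tol` (relative) are flagged as merge candidates, reported with
#' their mean coefficient — e.g. two APA durations loading 0.71 and 0.56
#' merge into a single "mean APA" term at 0.635.
#'
#' @param model A `gi_pca`.
#' @param components Number of leading components to summarize.
#' @param drop_below Display threshold on coefficient magnitude.
#' @param merge_tol Relative difference under which two kept coefficients
#'   are considered interchangeable.
#' @return Tibble with `component`, `feature`, `loading`, `kept`,
#'   `merge_group` (NA when not merged) and `merged_loading` (mean
#'   coefficient of the group).
#' @export
simplify_loadings <- function(model, components = 3, drop_below = 0.1,
                              merge_tol = 0.2) {
  stopifnot(inherits(model, "gi_pca"))
  components <- min(components, ncol(model$loadings))
  purrr::map_dfr(seq_len(components), function(j) {
    l <- model$loadings[, j]
    kept <- abs(l) >= drop_below
    out <- tibble(component = paste0("PC", j),
                  feature = names(l), loading = unname(l),
                  kept = kept,
                  merge_group = NA_integer_,
                  merged_loading = NA_real_)
    ki <- which(kept)
    if (length(ki) > 1) {
      ord <- ki[order(abs(l[ki]))]
      grp <- integer(length(ord))
      g <- 1L
      grp[1] <- g
      for (i in 2:length(ord)) {
        a <- abs(l[ord[i - 1]])
        b <- abs(l[ord[i]])
        if ((b - a) / b < merge_tol) grp[i] <- g else grp[i] <- (g <- g + 1L)
      }
      for (gg in unique(grp)) {
        members <- ord[grp == gg]
        if (length(members) > 1) {
          out$merge_group[members] <- gg
          out$merged_loading[members] <- mean(l[members])
        }
      }
    }
    out
  })
}

#' @export
print.gi_report <- function(x, ...) {
  cat("<gi_report> gait-initiation classification run\n")
  cat(sprintf("  %d participants, k = %d PCs retained (%.2f%% variance)\n",
              nrow(x$features), x$k,
              100 * x$explained$cumulative[x$k]))
  for (nm in names(x$subspaces)) {
    s <- x$subspaces[[nm]]
    cat(sprintf("  %s: Jaccard %.3f, GMM accuracy %s\n", nm, s$jaccard,
                paste(sprintf("%s %.1f%%", names(s$confusion$group_accuracy),
                              100 * s$confusion$group_accuracy),
                      collapse = ", ")))
  }
  invisible(x)
}

# serialize the run report and its CSV artifacts
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pca_to_json(report$pca, file.path(out_dir, "pca_model.json"))

  cloud_tbl <- purrr::map_dfr(report$clouds, function(cl) {
    dplyr::mutate(cl$means, group = cl$group, .before = 1)
  })
  utils::write.csv(cloud_tbl, file.path(out_dir, "cloud_means.csv"),
                   row.names = FALSE, quote = FALSE)

  for (i in seq_along(report$subspaces)) {
    s <- report$subspaces[[i]]
    fname <- sprintf("confusion_pc%s.csv",
                     gsub("[^0-9]", "", s$subspace))
    utils::write.csv(as.data.frame(s$confusion$percent),
                     file.path(out_dir, fname), quote = FALSE)
  }

  json <- list(
    version = report$version,
    seed = report$seed,
    config = report$config,
    k = report$k,
    explained_fraction = report$pca$explained_fraction,
    jaccard = as.list(report$jaccard),
    subspaces = purrr::map(report$subspaces, function(s) {
      list(jaccard = s$jaccard,
           gmm = list(weights = s$gmm$weights,
                      means = s$gmm$means,
                      converged = s$gmm$converged,
                      iterations = s$gmm$iterations,
                      loglik = s$gmm$loglik),
           confusion_percent = s$confusion$percent,
           accuracy = s$confusion$accuracy,
           group_accuracy = as.list(s$confusion$group_accuracy))
    }))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Read / write a cohort feature table as CSV
#'
#' Schema: `participant_id,group,<11 registry features>`.
#'
#' @param data Feature table.
#' @param path CSV path.
#' @return `path` invisibly; `read_cohort_csv()` returns the tibble.
#' @export
write_cohort_csv <- function(data, path) {
  check_feature_columns(data, gi_features())
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  check_feature_columns(out, gi_features())
  out
}
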