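#' Label-aligned confusion matrix for unsupervised clustering
#'
#' Cluster indices from an unsupervised fit are arbitrary, so before
#' cross-tabulating them against the true groups the cluster-to-group
#' mapping is chosen by optimal assignment: the permutation of cluster
#' labels that maximizes total agreement. Rows are then normalized to
#' percentages per true group, the form in which classification accuracy
#' is conventionally reported.
#'
#' @param true_groups Vector of true group labels.
#' @param cluster_labels Vector of cluster indices (same length).
#' @return A `gi_confusion`: list with `percent` (rows = true groups,
#'   columns = predicted groups, row sums 100), `counts`, `mapping`
#'   (cluster -> group), `accuracy` (overall fraction correct) and
#'   `group_accuracy` (named per-group diagonal, as fractions).
#' @export
#' @examples
#' truth <- rep(c("control", "pd"), each = 5)
#' align_and_confuse(truth, c(2, 2, 2, 2, 1, 1, 1, 1, 1, 1))
align_and_confuse <- function(true_groups, cluster_labels) {
  if (length(true_groups) != length(cluster_labels)) {
    abort("Label vectors must have the same length.")
  }
  groups <- sort(unique(as.character(true_groups)))
  clusters <- sort(unique(cluster_labels))
  if (length(clusters) > length(groups)) {
    abort(sprintf("More clusters (%d) than true groups (%d).",
                  length(clusters), length(groups)))
  }
  k <- length(groups)

  # optimal assignment over permutations (k is small: 2 in the headline
  # two-group analysis)
  perms <- permutations_of(seq_len(k))
  tab <- table(factor(as.character(true_groups), levels = groups),
               factor(cluster_labels, levels = clusters))
  best_agree <- -1L
  best_map <- NULL
  for (p in perms) {
    map <- stats::setNames(groups[p[seq_along(clusters)]], clusters)
    agree <- sum(vapply(seq_along(clusters),
                        function(j) tab[map[j], j], numeric(1)))
    if (agree > best_agree) {
      best_agree <- agree
      best_map <- map
    }
  }

  predicted <- factor(best_map[as.character(cluster_labels)], levels = groups)
  counts <- table(true = factor(as.character(true_groups), levels = groups),
                  predicted = predicted)
  counts <- matrix(as.numeric(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  percent <- sweep(counts, 1, rowSums(counts), "/") * 100
  ga <- diag(percent) / 100
  names(ga) <- groups

  structure(
    list(percent = percent, counts = counts,
         mapping = best_map,
         accuracy = sum(diag(as.matrix(counts))) / sum(counts),
         group_accuracy = ga),
    class = "gi_confusion")
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' @export
print.gi_confusion <- function(x, ...) {
  cat("<gi_confusion> row percentages (true group x predicted group)\n")
  print(round(x$percent, 1))
  cat(sprintf("overall accuracy: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' @rdname align_and_confuse
#' @param x A `gi_confusion`.
#' @param ... Unused.
#' @method tidy gi_confusion
#' @export
tidy.gi_confusion <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$percent))) |>
    stats::setNames(c("true", "predicted", "percent"))
}

#' @rdname align_and_confuse
#' @method glance gi_confusion
#' @export
glance.gi_confusion <- function(x, ...) {
  dplyr::bind_cols(tibble(accuracy = x$accuracy),
                   as_tibble(as.list(x$group_accuracy)))
}
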