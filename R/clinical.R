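# Cluster-wise DC extraction and correlation with clinical scores.

#' Construct a subject record
#'
#' @param id unique subject identifier.
#' @param group \code{"control"} or \code{"patient"}.
#' @param scores named numeric vector of clinical scores (e.g. HAMD, BDI,
#'   GAF, episode_weeks, duration_years, n_episodes).
#' @param ... additional handles (e.g. file paths or in-memory volumes).
#' @return an object of class \code{subject_record}.
#' @export
subject_record <- function(id, group = c("control", "patient"),
                           scores = numeric(0), ...) {
  group <- match.arg(group)
  scores <- unlist(scores)
  stopifnot(all(is.finite(scores) | is.na(scores)))
  structure(list(id = as.character(id), group = group, scores = scores, ...),
            class = "subject_record")
}

#' Read a subject table
#'
#' Tab-separated table with columns id, group, and score columns.
#'
#' @param path TSV file path.
#' @return list of \code{subject_record}s.
#' @export
read_subject_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "group") %in% names(df)))
  score_cols <- setdiff(names(df), c("id", "group"))
  lapply(seq_len(nrow(df)), function(i) {
    sc <- unlist(df[i, score_cols, drop = FALSE])
    subject_record(df$id[i], df$group[i], scores = sc)
  })
}

#' Write a subject table
#' @param records list of \code{subject_record}s.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_subject_table <- function(records, path) {
  score_names <- unique(unlist(lapply(records, function(r) names(r$scores))))
  df <- do.call(rbind, lapply(records, function(r) {
    row <- data.frame(id = r$id, group = r$group)
    for (s in score_names) {
      row[[s]] <- if (s %in% names(r$scores)) r$scores[[s]] else NA_real_
    }
    row
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract cluster-mean DC values per subject
#'
#' For each subject and each cluster, the mean of the subject's z-DC map over
#' the cluster's voxel set.
#'
#' @param dc_maps list of per-subject \code{dc_map}s (or 3D arrays) on the
#'   cluster grid.
#' @param clusters a \code{cluster_set} with at least one cluster, or a list
#'   of clusters.
#' @return matrix (subjects x clusters) of means; class
#'   \code{cluster_score_table}.
#' @export
extract_cluster_means <- function(dc_maps, clusters) {
  cls <- if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
  if (length(cls) == 0) stop("no clusters to extract from")
  n_vox <- min(vapply(dc_maps, function(m) {
    length(if (inherits(m, "dc_map")) m$data else as.array(m))
  }, numeric(1)))
  for (cl in cls) {
    if (any(cl$voxels > n_vox | cl$voxels < 1)) {
      stop("cluster voxel outside map grid")
    }
  }
  tab <- vapply(cls, function(cl) {
    vapply(dc_maps, function(m) {
      arr <- if (inherits(m, "dc_map")) m$data else as.array(m)
      mean(arr[cl$voxels])
    }, numeric(1))
  }, numeric(length(dc_maps)))
  tab <- matrix(tab, nrow = length(dc_maps))
  rownames(tab) <- names(dc_maps)
  colnames(tab) <- paste0("cluster", seq_along(cls))
  if (any(!is.finite(tab))) stop("non-finite cluster mean")
  class(tab) <- c("cluster_score_table", class(tab))
  tab
}

#' Correlate cluster-mean DC with a clinical score
#'
#' Pearson correlation between the per-subject cluster means and the named
#' clinical score, with two-sided p and Bonferroni adjustment
#' \code{p_adj = min(1, m * p)}. Computed over patients only: controls carry
#' no symptom scores, and pooling groups would manufacture group-driven
#' correlations.
#'
#' @param table a \code{cluster_score_table} whose rows follow
#'   \code{records}' order.
#' @param records list of \code{subject_record}s, same length and order as
#'   the table rows.
#' @param score_name name of the score to correlate.
#' @param bonferroni_m Bonferroni factor; by convention the number of bands
#'   with significant group findings upstream.
#' @return data.frame with one row per cluster: r, p, p_adj, n.
#' @export
correlate_with_scores <- function(table, records, score_name,
                                  bonferroni_m = 1L) {
  stopifnot(nrow(table) == length(records), bonferroni_m >= 1)
  grp <- vapply(records, function(r) r$group, character(1))
  sc <- vapply(records, function(r) {
    if (score_name %in% names(r$scores)) r$scores[[score_name]] else NA_real_
  }, numeric(1))
  use <- grp == "patient" & !is.na(sc)
  n_pat <- sum(grp == "patient")
  if (n_pat == 0) stop("no patients in the cohort")
  if (sum(use) < ceiling(n_pat / 2)) {
    stop("score '", score_name, "' missing for more than half the patients")
  }
  if (sum(use) < 4) stop("need at least 4 patients with score ", score_name)
  y <- sc[use]
  if (stats::sd(y) == 0) stop("score '", score_name, "' constant across patients")
  out <- do.call(rbind, lapply(seq_len(ncol(table)), function(j) {
    x <- table[use, j]
    if (stats::sd(x) == 0) stop("cluster mean constant across patients")
    ct <- stats::cor.test(x, y)
    data.frame(cluster = colnames(table)[j], r = unname(ct$estimate),
               p = ct$p.value,
               p_adj = min(1, bonferroni_m * ct$p.value), n = sum(use))
  }))
  rownames(out) <- NULL
  out
}
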