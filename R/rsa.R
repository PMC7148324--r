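# Representational similarity analysis: first-level RDMs (Euclidean over
# stimulus descriptors, dummy-coded categories, participant-averaged
# ratings) and second-level Spearman comparisons of RDM lower triangles.

.new_rdm <- function(m, ids, source, distance_kind) {
  dimnames(m) <- list(ids, ids)
  structure(list(matrix = m, stimulus_order = ids, source = source,
                 distance_kind = distance_kind),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %s (%s): %d x %d stimuli\n", x$source,
              x$distance_kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Euclidean representational dissimilarity matrix
#'
#' Entry (i, j) is the Euclidean distance between the descriptor of
#' stimulus i and stimulus j; for scalar descriptors this is the absolute
#' difference.
#'
#' @param values Numeric vector (one scalar per stimulus) or matrix
#'   (stimuli in rows).
#' @param ids Stimulus identifiers (defaults to names/rownames or indices).
#' @param source Descriptor name recorded on the RDM.
#' @return An object of class `rdm`.
#' @export
euclidean_rdm <- function(values, ids = NULL, source = "feature") {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values))
    stop_data("descriptor values must be numeric and complete")
  n <- nrow(values)
  if (n < 2L) stop_data("an RDM needs at least 2 stimuli")
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (length(ids) != n) stop_data("ids length does not match stimulus count")
  m <- as.matrix(stats::dist(values, method = "euclidean"))
  .new_rdm(m, ids, source, "euclidean")
}

#' Dummy-coded category dissimilarity matrix
#'
#' Stimuli with the same label have dissimilarity 0; stimuli with different
#' labels have sqrt(2), the Euclidean distance between distinct one-hot
#' category vectors.
#'
#' @param labels Per-stimulus category labels (no missing values).
#' @param ids Stimulus identifiers.
#' @param source Descriptor name recorded on the RDM.
#' @return An object of class `rdm`.
#' @export
dummy_rdm <- function(labels, ids = NULL, source = "emotion") {
  if (anyNA(labels)) stop_data("category labels contain missing values")
  n <- length(labels)
  if (n < 2L) stop_data("an RDM needs at least 2 stimuli")
  if (is.null(ids)) ids <- names(labels)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  m <- sqrt(2) * (outer(labels, labels, `!=`) + 0)
  .new_rdm(m, ids, source, "dummy")
}

#' Group-average RDMs of behavioural ratings
#'
#' For each scale question, a per-participant RDM of absolute rating
#' differences is built and the group RDM is the entrywise mean across
#' participants; for each forced-choice question, per-participant
#' dummy-coded RDMs are averaged. Every participant must have rated every
#' stimulus on every question (no imputation is performed).
#'
#' @param ratings A `rating_table`.
#' @return Named list of `rdm` objects, one per question.
#' @export
rating_rdms <- function(ratings) {
  stopifnot(inherits(ratings, "rating_table"))
  qs <- attr(ratings, "questions")
  if (is.null(qs)) qs <- rating_questions()
  stims <- unique(ratings$stimulus_id)
  parts <- sort(unique(ratings$participant))
  out <- list()
  for (q in qs$scale) {
    m <- rating_matrix(ratings, q)  # errors on holes
    m <- m[, stims, drop = FALSE]
    acc <- matrix(0, length(stims), length(stims))
    for (p in seq_len(nrow(m)))
      acc <- acc + abs(outer(m[p, ], m[p, ], `-`))
    out[[q]] <- .new_rdm(acc / nrow(m), stims, q, "euclidean")
  }
  for (q in qs$categorical) {
    sub <- ratings[ratings$question == q & ratings$type == "categorical", ]
    if (!nrow(sub)) stop_data("no responses for question '%s'", q)
    cm <- matrix(NA_character_, length(parts), length(stims),
                 dimnames = list(parts, stims))
    cm[cbind(match(sub$participant, parts),
             match(sub$stimulus_id, stims))] <- sub$choice
    if (anyNA(cm)) {
      holes <- which(is.na(cm), arr.ind = TRUE)
      stop_data("missing responses for question '%s': %s", q,
                paste(sprintf("participant %s / %s",
                              rownames(cm)[holes[, 1]],
                              colnames(cm)[holes[, 2]])[seq_len(min(5, nrow(holes)))],
                      collapse = "; "))
    }
    acc <- matrix(0, length(stims), length(stims))
    for (p in seq_len(nrow(cm)))
      acc <- acc + sqrt(2) * (outer(cm[p, ], cm[p, ], `!=`) + 0)
    out[[q]] <- .new_rdm(acc / nrow(cm), stims, q, "dummy")
  }
  out
}

.lower_tri <- function(rdm) rdm$matrix[lower.tri(rdm$matrix, diag = FALSE)]

#' Second-level Spearman comparison of two RDMs
#'
#' Spearman's rank correlation over the strictly-lower-triangle entries of
#' the two matrices (the diagonal carries no information); ties receive
#' average ranks. The two-sided p-value uses the t approximation with
#' `df = n(n-1)/2 - 2`.
#'
#' @param a,b `rdm` objects over the same stimuli in the same order.
#' @param m Number of comparisons used for the Bonferroni-corrected
#'   p-value (default 1, i.e. no correction).
#' @param method `"t"` for the t approximation or `"permutation"` for a
#'   stimulus-relabelling permutation p-value.
#' @param n_perm,seed Permutation count and seed when
#'   `method = "permutation"`.
#' @return An object of class `rdm_comparison` with `rho`, `df`, `p_raw`,
#'   `p_bonferroni` and `m_comparisons`.
#' @export
compare_rdms <- function(a, b, m = 1L, method = c("t", "permutation"),
                         n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(a, "rdm"), inherits(b, "rdm"))
  method <- match.arg(method)
  if (length(a$stimulus_order) != length(b$stimulus_order) ||
      !all(a$stimulus_order == b$stimulus_order))
    stop_data("RDMs are not over the same stimuli in the same order")
  x <- .lower_tri(a); y <- .lower_tri(b)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_data("undefined correlation: an RDM lower triangle has zero variance")
  rho <- stats::cor(x, y, method = "spearman")
  df <- length(x) - 2L
  if (method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt(df / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df)
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(a$matrix)
    rx <- rank(x)
    count <- 0L
    for (i in seq_len(n_perm)) {
      perm <- sample.int(n)
      mp <- b$matrix[perm, perm]
      yp <- mp[lower.tri(mp)]
      if (abs(stats::cor(rx, rank(yp))) >= abs(rho) - 1e-12) count <- count + 1L
    }
    p <- (count + 1L) / (n_perm + 1L)
  }
  structure(list(rho = rho, df = df, p_raw = p,
                 p_bonferroni = min(1, p * m), m_comparisons = m,
                 items = c(a$source, b$source), method = method),
            class = "rdm_comparison")
}

#' @export
print.rdm_comparison <- function(x, ...) {
  cat(sprintf("<rdm_comparison> %s ~ %s: rho(%d) = %.3f, p = %.4g (Bonferroni x%d: %.4g)\n",
              x$items[1], x$items[2], x$df, x$rho, x$p_raw,
              x$m_comparisons, x$p_bonferroni))
  invisible(x)
}

#' Pairwise second-level comparison matrix
#'
#' Compares every pair of RDMs with [compare_rdms] and stores the result as
#' a symmetric `1 - rho` distance matrix with a zero diagonal, together
#' with Bonferroni-corrected (`alpha = 0.05 / m_per_item`) and uncorrected
#' (`alpha = 0.05`) significance masks.
#'
#' @param rdms Named list of at least two `rdm` objects with identical
#'   stimulus orders.
#' @param m_per_item Bonferroni divisor per item (e.g. 9 for the computed
#'   feature analysis, 12 for the behavioural rating analysis).
#' @return An object of class `second_level` with matrices
#'   `one_minus_rho`, `rho`, `p_raw`, and logical masks `sig_bonferroni`,
#'   `sig_uncorrected`.
#' @export
second_level_matrix <- function(rdms, m_per_item) {
  if (length(rdms) < 2L) stop_data("need at least 2 RDMs")
  nm <- names(rdms)
  if (is.null(nm)) nm <- vapply(rdms, `[[`, character(1), "source")
  k <- length(rdms)
  rho <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    cmp <- compare_rdms(rdms[[i]], rdms[[j]], m = m_per_item)
    rho[i, j] <- rho[j, i] <- cmp$rho
    p[i, j] <- p[j, i] <- cmp$p_raw
  }
  omr <- 1 - rho
  diag(omr) <- 0
  structure(list(one_minus_rho = omr, rho = rho, p_raw = p,
                 sig_bonferroni = p < 0.05 / m_per_item,
                 sig_uncorrected = p < 0.05,
                 m_per_item = m_per_item,
                 df = length(.lower_tri(rdms[[1]])) - 2L),
            class = "second_level")
}

#' @export
print.second_level <- function(x, ...) {
  cat(sprintf("<second_level> %d RDMs, df = %d, Bonferroni alpha = 0.05/%d\n",
              nrow(x$rho), x$df, x$m_per_item))
  print(round(x$one_minus_rho, 3))
  invisible(x)
}

#' Cross comparisons between two RDM collections
#'
#' Compares every RDM of `rdms_a` against every RDM of `rdms_b` (e.g.
#' behavioural-rating RDMs against computed-feature RDMs).
#'
#' @param rdms_a,rdms_b Named lists of `rdm` objects.
#' @param m_per_item Bonferroni divisor applied to each comparison.
#' @return Data frame with columns `item_a`, `item_b`, `rho`, `df`,
#'   `p_raw`, `p_bonferroni`.
#' @export
cross_rdm_table <- function(rdms_a, rdms_b, m_per_item = 1L) {
  rows <- list()
  for (a in names(rdms_a)) for (b in names(rdms_b)) {
    cmp <- compare_rdms(rdms_a[[a]], rdms_b[[b]], m = m_per_item)
    rows[[length(rows) + 1L]] <- data.frame(
      item_a = a, item_b = b, rho = cmp$rho, df = cmp$df,
      p_raw = cmp$p_raw, p_bonferroni = cmp$p_bonferroni,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write an RDM as square CSV with a JSON sidecar
#'
#' @param rdm An `rdm`.
#' @param path CSV path; metadata goes to `paste0(path, ".meta.json")`.
#' @return `path`, invisibly.
#' @export
write_rdm <- function(rdm, path) {
  stopifnot(inherits(rdm, "rdm"))
  utils::write.csv(as.data.frame(rdm$matrix), path, row.names = TRUE)
  jsonlite::write_json(list(source = rdm$source,
                            distance_kind = rdm$distance_kind,
                            n = nrow(rdm$matrix)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
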