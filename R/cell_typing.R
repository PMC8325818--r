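## Probabilistic cell typing: Poisson-likelihood Bayesian classification of
## segmented cells against scRNA-seq class mean-expression profiles.

#' Probabilistic cell typing against scRNA-seq class means
#'
#' Assigns each segmented cell a posterior probability over reference cell
#' classes under an independent-Poisson model of its gene counts. For cell
#' `c` with counts `n_cg`, a per-cell scale factor
#' `s_c = sum_g n_cg / median_k sum_g mu_kg` absorbs capture depth, and the
#' class log-likelihood (up to a count-only constant) is
#' `L(c,k) = sum_g [ n_cg log(s_c mu_kg + eps) - (s_c mu_kg + eps) ]`,
#' with `eps` a small pseudo-expression guarding `log 0`. Posteriors are
#' `prior_k exp(L(c,k))` normalized per cell with the log-sum-exp guard.
#'
#' This is the cell-level reduction of probabilistic cell typing by in situ
#' sequencing: spot-level reassignment, misread/background spot modeling and
#' gene-efficiency re-estimation are deliberately not modeled.
#'
#' @param seg a [segmented_map] with `unit_kind = "cell"` (bins work too,
#'   typing "pseudo-cells").
#' @param ref a [class_reference]; genes are aligned to the intersection
#'   with the panel (warning below 5 shared genes). Classes whose means are
#'   all zero are excluded with a warning.
#' @param priors named per-class prior weights (any positive scale), or
#'   `NULL` for uniform.
#' @param epsilon pseudo-expression added to every expected count
#'   (default 0.1 reads).
#' @param scale optional per-cell scale factor(s) overriding the internal
#'   `s_c` (recycled if scalar); useful when depth is known externally.
#' @return An object of class `typing_result`: `probabilities` (cells x
#'   classes, rows summing to 1), hard assignment `class` (argmax, ties to
#'   the first class in reference order), `counts` echo on the shared genes,
#'   `scale` (`s_c`), `priors`, `epsilon`, and logical `flagged` marking
#'   zero-read cells (their posterior is the prior).
#' @export
pciseq_assign <- function(seg, ref, priors = NULL, epsilon = 0.1,
                          scale = NULL) {
  stopifnot(inherits(seg, "segmented_map"), inherits(ref, "class_reference"))
  shared <- intersect(colnames(seg$counts), colnames(ref$means))
  if (length(shared) == 0L) stop("no shared genes between cells and reference")
  if (length(shared) < 5L)
    warning("only ", length(shared), " shared gene(s); typing will be weak")
  counts <- seg$counts[, shared, drop = FALSE]
  mu <- ref$means[, shared, drop = FALSE]
  keep <- rowSums(mu) > 0
  if (!all(keep)) {
    warning("class(es) with all-zero means excluded: ",
            paste(rownames(mu)[!keep], collapse = ", "))
    mu <- mu[keep, , drop = FALSE]
  }
  K <- nrow(mu)
  if (K < 2L) stop("need at least 2 usable reference classes")
  classes <- rownames(mu)
  if (is.null(priors)) priors <- setNames(rep(1, K), classes)
  priors <- priors[classes]
  if (anyNA(priors) || any(priors <= 0))
    stop("priors must be positive and named for every class")
  nc <- nrow(counts)
  tot <- rowSums(counts)
  s <- if (is.null(scale)) tot / stats::median(rowSums(mu))
       else rep_len(scale, nc)
  L <- matrix(0, nc, K, dimnames = list(rownames(counts), classes))
  for (k in seq_len(K)) {
    lam <- outer(s, mu[k, ]) + epsilon           # cells x genes
    L[, k] <- rowSums(counts * log(lam) - lam)
  }
  L <- sweep(L, 2, log(priors / sum(priors)), "+")
  # log-sum-exp normalization per cell
  m <- apply(L, 1, max)
  post <- exp(L - m)
  post <- post / rowSums(post)
  flagged <- tot == 0
  if (any(flagged)) post[flagged, ] <- rep(priors / sum(priors),
                                           each = sum(flagged))
  hard <- classes[apply(post, 1, which.max)]
  structure(list(probabilities = post, class = hard, counts = counts,
                 scale = s, priors = priors / sum(priors),
                 epsilon = epsilon, flagged = flagged),
            class = "typing_result")
}

#' @export
print.typing_result <- function(x, ...) {
  cat(sprintf("typing_result: %d cells x %d classes (epsilon = %g)\n",
              nrow(x$probabilities), ncol(x$probabilities), x$epsilon))
  print(table(x$class))
  invisible(x)
}

#' Cell-class composition of spatial domains
#'
#' Cross-tabulates hard cell-type assignments against a domain (cluster)
#' assignment of the same cells and normalizes each domain row to 1.
#'
#' @param typing a `typing_result`.
#' @param domains a `cluster_assignment` aligned to the same cells, or an
#'   integer/character vector of domain ids per cell.
#' @return A domains x classes frequency matrix; rows sum to 1, a domain
#'   with no cells yields a zero row with a warning.
#' @export
class_composition <- function(typing, domains) {
  stopifnot(inherits(typing, "typing_result"))
  dom <- if (inherits(domains, "cluster_assignment")) domains$cluster
         else domains
  if (length(dom) != length(typing$class))
    stop("domains must align with the typed cells")
  dl <- sort(unique(dom))
  classes <- colnames(typing$probabilities)
  tab <- table(factor(dom, levels = dl),
               factor(typing$class, levels = classes))
  freq <- matrix(as.numeric(tab), length(dl), length(classes),
                 dimnames = list(dl, classes))
  tot <- rowSums(freq)
  if (any(tot == 0)) warning("domain(s) with no cells: zero row(s) reported")
  freq / ifelse(tot == 0, 1, tot)
}

#' Gene-normalized mean expression per assigned class
#'
#' Mean counts of the cells hard-assigned to each class, then each gene
#' column normalized by its total over classes, highlighting which class a
#' gene is enriched in.
#'
#' @param typing a `typing_result`.
#' @param seg the [segmented_map] that was typed.
#' @return A classes x genes matrix whose nonzero gene columns sum to 1.
#' @export
typing_means <- function(typing, seg) {
  stopifnot(inherits(typing, "typing_result"),
            inherits(seg, "segmented_map"))
  counts <- seg$counts[, colnames(typing$counts), drop = FALSE]
  classes <- colnames(typing$probabilities)
  means <- matrix(0, length(classes), ncol(counts),
                  dimnames = list(classes, colnames(counts)))
  for (k in classes) {
    sel <- typing$class == k
    if (any(sel)) means[k, ] <- colMeans(counts[sel, , drop = FALSE])
  }
  tot <- colSums(means)
  sweep(means, 2, ifelse(tot == 0, 1, tot), "/")
}

#' Spatial map of the most probable cell class
#'
#' @param typing a `typing_result`.
#' @param seg the typed [segmented_map] (provides centroids).
#' @param ... passed to [graphics::points()].
#' @export
plot_typing_map <- function(typing, seg, ...) {
  classes <- colnames(typing$probabilities)
  pal <- grDevices::colorRampPalette(
    c("firebrick", "orange", "gold", "forestgreen", "royalblue", "purple",
      "deeppink"))(length(classes))
  cols <- pal[match(typing$class, classes)]
  graphics::plot(seg$centroids[, "x"], -seg$centroids[, "y"], col = cols,
                 pch = 16, cex = 0.6, asp = 1, xlab = "x (px)",
                 ylab = "-y (px)", main = "cell classes", ...)
  graphics::legend("topright", classes, col = pal, pch = 16, cex = 0.6,
                   bty = "n")
}
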