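#' Define variable groups by average-linkage clustering of the correlation
#' matrix
#'
#' Variables are clustered with average linkage on the dissimilarity
#' `1 - |Sigma_ij|` and the tree is cut so that two variables end up in the
#' same group only when their cophenetic dissimilarity is strictly below
#' `1 - cutoff`; with the conventional `cutoff = 0.5` this merges variables
#' with absolute correlation above 0.5, the standard rule for LD-based SNP
#' grouping. Groups are relabeled so that, after the stored canonical
#' permutation, the indices of each group are contiguous (a requirement of the
#' block-diagonal S parameterization).
#'
#' @param model a [correlation_model()].
#' @param cutoff correlation cutoff in (0, 1); default 0.5.
#' @return An object of class `group_partition` with fields
#'   `assignment` (length-p labels 1..g, in original variable order),
#'   `groups` (list of index sets in the canonical order),
#'   `perm` (canonical permutation: `perm[k]` is the original index placed at
#'   canonical position k) and `g`.
#' @export
hierarchical_cluster_groups <- function(model, cutoff = 0.5) {
  stopifnot(inherits(model, "correlation_model"))
  if (cutoff <= 0 || cutoff >= 1) gk_stop("cutoff must lie in (0, 1)")
  p <- model$p
  if (p == 1) {
    return(new_group_partition(1L, p))
  }
  d <- as.dist(1 - abs(model$sigma))
  hc <- hclust(d, method = "average")
  # cutree merges ties at the cut height; back off to keep the cut strict so
  # that pairs at exactly |r| = cutoff stay separate
  lab <- cutree(hc, h = (1 - cutoff) - 1e-9)
  new_group_partition(as.integer(lab), p)
}

#' Construct a group partition from explicit labels
#'
#' @param assignment integer vector of group labels for each variable (any
#'   labeling; relabeled 1..g in order of first appearance along the canonical
#'   permutation).
#' @param p number of variables.
#' @return A `group_partition`.
#' @export
new_group_partition <- function(assignment, p = length(assignment)) {
  assignment <- as.integer(assignment)
  if (length(assignment) != p) gk_stop("assignment length must equal p")
  if (anyNA(assignment)) gk_stop("assignment contains NA")
  # canonical order: sort variables by group label (stable), making each
  # group's indices contiguous; relabel groups 1..g in canonical order
  perm <- order(assignment)
  lab_sorted <- assignment[perm]
  new_lab <- cumsum(c(1L, diff(lab_sorted) != 0L))
  assignment_new <- integer(p)
  assignment_new[perm] <- new_lab
  g <- max(new_lab)
  groups <- split(seq_len(p), new_lab)  # canonical positions 1..p
  names(groups) <- NULL
  structure(list(assignment = assignment_new, groups = groups,
                 perm = perm, g = g),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat(sprintf("<group_partition> p = %d, g = %d groups (sizes %d..%d)\n",
              length(x$assignment), x$g, min(sizes), max(sizes)))
  invisible(x)
}

# Reorder a correlation model into the canonical (contiguous-group) order.
canonical_sigma <- function(model, partition) {
  model$sigma[partition$perm, partition$perm, drop = FALSE]
}

#' Select key variables within each group
#'
#' Within each group, greedily selects "key" variables until they explain at
#' least a fraction `c` of the within-group variation: the explained variance
#' of a key set K is `EV(K) = sum_j Sigma[j,K] Sigma[K,K]^-1 Sigma[K,j]` over
#' group members j (the sum of within-group R-squared values), and selection
#' stops when `EV(K) / |group| >= c`. The remaining ("non-key") variables are
#' then treated as conditionally independent of everything outside their group
#' given the keys, which shrinks the knockoff optimization problem. `c = 1`
#' disables the conditional-independence shortcut: every variable is key.
#'
#' @param model a [correlation_model()] (regularized, so group blocks are
#'   nonsingular).
#' @param partition a `group_partition` for the same variables.
#' @param c target fraction of within-group variation explained, in (0, 1].
#' @return An object of class `key_selection` with per-group canonical index
#'   sets `star` (keys) and `dagger` (non-keys), plus `c` and the partition.
#' @export
select_key_variables <- function(model, partition, c = 0.5) {
  stopifnot(inherits(model, "correlation_model"),
            inherits(partition, "group_partition"))
  if (c <= 0 || c > 1) gk_stop("c must lie in (0, 1]")
  sig <- canonical_sigma(model, partition)
  star <- vector("list", partition$g)
  dagger <- vector("list", partition$g)
  for (gi in seq_len(partition$g)) {
    idx <- partition$groups[[gi]]
    if (c == 1 || length(idx) == 1) {
      star[[gi]] <- idx
      dagger[[gi]] <- integer(0)
      next
    }
    sg <- sig[idx, idx, drop = FALSE]
    b <- length(idx)
    keys <- integer(0)
    repeat {
      remaining <- setdiff(seq_len(b), keys)
      ev_try <- vapply(remaining, function(v) {
        kk <- c(keys, v)
        skk <- sg[kk, kk, drop = FALSE]
        cross <- sg[, kk, drop = FALSE]
        sum(cross * t(solve(skk, t(cross))))
      }, numeric(1))
      best <- remaining[which.max(ev_try)]  # which.max: ties -> lowest index
      keys <- c(keys, best)
      if (max(ev_try) / b >= c - 1e-12 || length(keys) == b) break
    }
    star[[gi]] <- idx[sort(keys)]
    dagger[[gi]] <- idx[sort(setdiff(seq_len(b), keys))]
  }
  new_key_selection(partition, star, dagger, c)
}

#' Construct a key selection from explicit per-group index sets
#'
#' @param partition a `group_partition`.
#' @param star list of canonical index vectors (keys), one per group, each
#'   non-empty.
#' @param dagger list of canonical index vectors (non-keys); defaults to the
#'   complement within each group.
#' @param c nominal explained-variance fraction (bookkeeping).
#' @return A `key_selection`.
#' @export
new_key_selection <- function(partition, star, dagger = NULL, c = NA_real_) {
  if (is.null(dagger)) {
    dagger <- lapply(seq_len(partition$g), function(gi) {
      setdiff(partition$groups[[gi]], star[[gi]])
    })
  }
  for (gi in seq_len(partition$g)) {
    a <- partition$groups[[gi]]
    if (length(star[[gi]]) == 0) gk_stop("group ", gi, " has no key variables")
    if (!setequal(union(star[[gi]], dagger[[gi]]), a) ||
        length(intersect(star[[gi]], dagger[[gi]])) > 0) {
      gk_stop("star/dagger do not partition group ", gi)
    }
  }
  structure(list(partition = partition, star = star, dagger = dagger, c = c),
            class = "key_selection")
}

#' @export
print.key_selection <- function(x, ...) {
  cat(sprintf("<key_selection> c = %s, %d keys of %d variables\n",
              format(x$c), sum(lengths(x$star)),
              length(x$partition$assignment)))
  invisible(x)
}

#' Within-group conditional regressions of non-key on key variables
#'
#' For each group, computes the Gaussian conditional law of the non-key
#' variables given the keys, using only the within-group block of the
#' correlation matrix: coefficients `B = Sigma[dagger, star] /
#' Sigma[star, star]` and residual covariance
#' `R = Sigma[dagger, dagger] - B Sigma[star, dagger]` (a Schur complement,
#' hence positive semidefinite). Under group-key conditional independence the
#' conditional law of a group's non-keys given all keys genome-wide reduces to
#' exactly this within-group regression.
#'
#' @param model a [correlation_model()].
#' @param keys a [select_key_variables()] result.
#' @return An object of class `conditional_regression`: lists `B` and `R`
#'   indexed by group (empty matrices where a group has no non-keys).
#' @export
conditional_regressions <- function(model, keys) {
  stopifnot(inherits(keys, "key_selection"))
  part <- keys$partition
  sig <- canonical_sigma(model, part)
  B <- vector("list", part$g)
  R <- vector("list", part$g)
  for (gi in seq_len(part$g)) {
    st <- keys$star[[gi]]
    dg <- keys$dagger[[gi]]
    if (length(dg) == 0) {
      B[[gi]] <- matrix(0, 0, length(st))
      R[[gi]] <- matrix(0, 0, 0)
      next
    }
    sss <- sig[st, st, drop = FALSE]
    sds <- sig[dg, st, drop = FALSE]
    Bg <- t(solve(sss, t(sds)))
    Rg <- sig[dg, dg, drop = FALSE] - Bg %*% t(sds)
    B[[gi]] <- Bg
    R[[gi]] <- (Rg + t(Rg)) / 2
  }
  structure(list(B = B, R = R, keys = keys), class = "conditional_regression")
}

#' Covariance implied by exact group-key conditional independence
#'
#' Returns the correlation matrix of the Gaussian distribution that exactly
#' satisfies group-key conditional independence with the given key sets while
#' preserving every within-group block and the joint law of all key variables:
#' cross-group entries involving non-key variables are routed through the key
#' variables of their group(s). The operation is idempotent and preserves
#' symmetry, the unit diagonal, and positive semidefiniteness.
#'
#' @param model a [correlation_model()].
#' @param keys a `key_selection`.
#' @return A `correlation_model` in the original variable order.
#' @export
ci_implied_sigma <- function(model, keys) {
  stopifnot(inherits(keys, "key_selection"))
  part <- keys$partition
  p <- model$p
  sig <- canonical_sigma(model, part)
  reg <- conditional_regressions(model, keys)
  # T: group-block-diagonal projector; key rows are identity, non-key rows
  # regress on their group's keys
  Tm <- diag(p)
  for (gi in seq_len(part$g)) {
    dg <- keys$dagger[[gi]]
    if (length(dg) == 0) next
    st <- keys$star[[gi]]
    Tm[dg, ] <- 0
    Tm[dg, st] <- reg$B[[gi]]
  }
  out <- Tm %*% sig %*% t(Tm)
  for (gi in seq_len(part$g)) {
    idx <- part$groups[[gi]]
    out[idx, idx] <- sig[idx, idx]
  }
  out <- (out + t(out)) / 2
  # map back to original order
  inv <- order(part$perm)
  out <- out[inv, inv, drop = FALSE]
  diag(out) <- 1
  correlation_model(out, meta = model$meta, gamma = model$gamma)
}

#' Write a group/key table
#'
#' Writes a TSV with columns `id chr pos group is_key` (group labels 1-based,
#' `is_key` in 0/1), in the original variable order.
#'
#' @param model a [correlation_model()] carrying variant metadata (falls back
#'   to `v1..vp` ids when absent).
#' @param keys a `key_selection`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_groups <- function(model, keys, path) {
  part <- keys$partition
  p <- model$p
  meta <- model$meta
  if (is.null(meta)) {
    meta <- data.frame(id = paste0("v", seq_len(p)), chr = "NA",
                       pos = seq_len(p))
  }
  is_key <- integer(p)
  canon_keys <- unlist(keys$star)
  orig_keys <- part$perm[canon_keys]
  is_key[orig_keys] <- 1L
  df <- data.frame(id = meta$id, chr = meta$chr, pos = meta$pos,
                   group = part$assignment, is_key = is_key)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
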