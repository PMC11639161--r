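#' Read a dense correlation/LD matrix from whitespace-delimited text
#'
#' @param path matrix file (no header, no row names).
#' @param meta_path optional variant metadata TSV with header `id chr pos`.
#' @return A [correlation_model()].
#' @export
read_sigma <- function(path, meta_path = NULL) {
  sig <- as.matrix(read.table(path, header = FALSE))
  dimnames(sig) <- NULL
  # symmetrize away printing round-off before validation
  sig <- (sig + t(sig)) / 2
  meta <- if (!is.null(meta_path)) read_variant_meta(meta_path) else NULL
  correlation_model(sig, meta = meta)
}

#' Write a dense matrix as whitespace-delimited text
#'
#' @param mat matrix.
#' @param path output path.
#' @param digits significant digits retained (default 17, lossless for
#'   doubles).
#' @return The path, invisibly.
#' @export
write_sigma <- function(mat, path, digits = 17) {
  write.table(format(mat, digits = digits, scientific = TRUE),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_variant_meta <- function(path) {
  meta <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  need <- c("id", "chr", "pos")
  if (!all(need %in% names(meta))) {
    gk_stop("metadata must have columns id, chr, pos")
  }
  meta
}

#' Read marginal Z-scores and align them to variant metadata
#'
#' Expects a TSV with header columns `id` and `z` (extra columns are
#' ignored). When `meta` is supplied the scores are reordered to match it;
#' ids present in the file but absent from the metadata (or vice versa) raise
#' a structured error listing them.
#'
#' @param path Z-score TSV.
#' @param meta optional variant metadata data.frame (`id`, `chr`, `pos`).
#' @return data.frame with columns `id`, `z`, ordered like `meta` when given.
#' @export
read_zscores <- function(path, meta = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("id", "z") %in% names(df))) {
    gk_stop("z-score file must have columns id, z")
  }
  if (anyDuplicated(df$id)) {
    gk_stop("duplicate ids in z-score file: ",
            paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (!is.numeric(df$z)) gk_stop("non-numeric z column")
  if (!is.null(meta)) {
    missing_ids <- setdiff(meta$id, df$id)
    extra_ids <- setdiff(df$id, meta$id)
    if (length(missing_ids) || length(extra_ids)) {
      gk_stop("z-score ids do not match metadata; missing: [",
              paste(missing_ids, collapse = ", "), "], unmatched: [",
              paste(extra_ids, collapse = ", "), "]")
    }
    df <- df[match(meta$id, df$id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df[, c("id", "z")]
}

#' Write ghost knockoff Z-scores as TSV
#'
#' Columns `id copy z_knockoff`, copy-major.
#'
#' @param sample a ghost `knockoff_sample`.
#' @param ids variant ids (length p).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_ghost_zscores <- function(sample, ids, path) {
  p <- length(ids)
  m <- sample$m
  df <- data.frame(id = rep(ids, m), copy = rep(seq_len(m), each = p),
                   z_knockoff = as.numeric(sample$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a knockoff solution: S matrix plus JSON sidecar
#'
#' The S matrix goes to `path` as dense text; `path` + `.json` records the
#' method, number of copies, objective trace, feasibility slacks and (for the
#' equivariant method) tau.
#'
#' @param solution a `knockoff_solution`.
#' @param path output path for the matrix.
#' @return The path, invisibly.
#' @export
write_solution <- function(solution, path) {
  write_sigma(solution$S, path)
  meta <- list(method = solution$method, m = solution$m,
               p = nrow(solution$S),
               objective_trace = solution$objective_trace,
               slack = as.list(solution$slack))
  if (!is.null(solution$gamma_equi)) meta$tau <- solution$gamma_equi
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write per-group filter results as TSV
#'
#' Columns `group rep_id chr pos Z W kappa tau selected q`; `rep_id` is the
#' most important variant in the group by `|beta|` (ties to the lowest
#' index).
#'
#' @param result a `filter_result`.
#' @param importance the importance list (`Z`, `Zt`, `beta`) that produced it.
#' @param groups group index sets (original order).
#' @param meta optional variant metadata.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_results <- function(result, importance, groups, meta = NULL, path) {
  g <- length(groups)
  rep_idx <- vapply(groups, function(idx) {
    idx[which.max(abs(importance$beta[idx]))]
  }, integer(1))
  if (is.null(meta)) {
    meta <- data.frame(id = paste0("v", seq_len(max(unlist(groups)))),
                       chr = "NA", pos = seq_len(max(unlist(groups))))
  }
  df <- data.frame(group = seq_len(g), rep_id = meta$id[rep_idx],
                   chr = meta$chr[rep_idx], pos = meta$pos[rep_idx],
                   Z = importance$Z, W = result$scores$W,
                   kappa = result$scores$kappa, tau = result$scores$tau,
                   selected = as.integer(seq_len(g) %in% result$selected),
                   q = result$q)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numeric where possible. Round-trips losslessly with
#' [write_run_config()].
#'
#' @param path config path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) gk_stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a flat key=value configuration file
#'
#' @param config named list of scalars.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", format(config[[k]], digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
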