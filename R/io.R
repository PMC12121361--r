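#' Read a protein-expression table
#'
#' Delimited text (tab or comma, auto-detected), first column protein
#' identifiers, header row sample identifiers; empty cells and `NA` are
#' missing. Proteins are rows, matching the model's orientation; use
#' `transpose = TRUE` for samples-as-rows files.
#'
#' @param path file path.
#' @param transpose transpose after reading; default `FALSE`.
#' @return numeric matrix with `NA` for missing entries.
#' @export
read_expression <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicated protein id(s): ", paste(unique(dup), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      if (length(bad) > 0)
        stop("non-numeric cell at row ", bad[1], ", column ",
             colnames(vals)[j])
      vals[[j]] <- as.numeric(col)
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- ids
  if (anyDuplicated(colnames(x)))
    stop("duplicated sample id(s) in header")
  if (transpose) t(x) else x
}

#' Write a protein-expression table
#' @param x numeric matrix, proteins in rows.
#' @param path output path (tab-delimited).
#' @export
write_expression <- function(x, path) {
  df <- data.frame(protein_id = rownames(x) %||%
                     as.character(seq_len(nrow(x))),
                   x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style edge list
#'
#' Three delimited columns: protein A, protein B, combined score. Scores may
#' be in `[0, 1]` or in the STRING 0-1000 integer dialect (auto-detected and
#' divided by 1000). Self-loops are dropped with a message. A header row is
#' detected by a non-numeric third field.
#'
#' @param path file path.
#' @return data frame `protein_a`, `protein_b`, `combined_score` with scores
#'   in `[0, 1]`.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("edge list needs 3 columns")
  df <- df[, 1:3]
  names(df) <- c("protein_a", "protein_b", "combined_score")
  s <- df$combined_score
  if (!is.numeric(s)) stop("combined_score column is not numeric")
  if (any(s < 0)) stop("negative combined score")
  if (any(s > 1)) {
    if (any(s > 1000)) stop("combined scores exceed both the [0,1] and 0-1000 dialects")
    df$combined_score <- s / 1000
  }
  self <- df$protein_a == df$protein_b
  if (any(self)) {
    message(sum(self), " self-loop(s) dropped")
    df <- df[!self, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a label table
#'
#' First column sample identifiers, remaining columns 0/1 biomarker labels.
#'
#' @param path file path (tab or comma delimited, auto-detected).
#' @return `n x B` integer matrix with sample row names.
#' @export
read_labels <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicated sample id(s) in label file")
  y <- as.matrix(df[, -1, drop = FALSE])
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  storage.mode(y) <- "integer"
  rownames(y) <- ids
  y
}

#' Write a label table
#' @param labels `n x B` 0/1 matrix with sample row names.
#' @param path output path (comma delimited).
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(sample_id = rownames(labels) %||%
                     as.character(seq_len(nrow(labels))),
                   labels, check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write network edges and statistics
#' @param network weight matrix.
#' @param path output TSV path for the weighted edge list.
#' @param stats_path optional JSON path for [network_stats()].
#' @export
write_network <- function(network, path, stats_path = NULL) {
  W <- as_weight_matrix(network)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  ids <- rownames(W) %||% as.character(seq_len(nrow(W)))
  df <- data.frame(protein_a = ids[idx[, 1]], protein_b = ids[idx[, 2]],
                   weight = W[upper.tri(W) & W > 0])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(stats_path))
    jsonlite::write_json(network_stats(W), stats_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Serialize a fitted model to a JSON bundle
#'
#' Protein-id-keyed `phi` and per-biomarker `theta` tables, covariate
#' weights when present, the loss trace and the control settings. The
#' network and training data are not embedded; keep them alongside.
#'
#' @param object a fitted `"gpnet"`.
#' @param path output JSON path.
#' @export
write_gpnet <- function(object, path) {
  stopifnot(inherits(object, "gpnet"))
  ids <- object$protein_ids %||% as.character(seq_along(object$phi))
  bundle <- list(
    package = "ppirisk",
    biomarkers = as.list(object$biomarkers),
    protein_ids = as.list(ids),
    phi = as.list(stats::setNames(unname(object$phi), ids)),
    theta = lapply(stats::setNames(object$biomarkers, object$biomarkers),
                   function(b) as.list(stats::setNames(object$theta[, b], ids))),
    beta = if (is.null(object$beta)) NULL else
      lapply(stats::setNames(object$biomarkers, object$biomarkers),
             function(b) as.list(object$beta[, b])),
    covariate_center = object$covariate_center,
    covariate_scale = object$covariate_scale,
    delta = object$delta,
    control = unclass(object$control),
    epochs = object$epochs,
    converged = object$converged,
    loss_trace = object$loss_trace
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a fitted model from a JSON bundle
#'
#' The returned object supports [predict.gpnet()] when a network is
#' attached; the training synergy and labels are not restored.
#'
#' @param path JSON path written by [write_gpnet()].
#' @param network optional weight matrix to attach for prediction.
#' @return a `"gpnet"` object (without training data).
#' @export
read_gpnet <- function(path, network = NULL) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- as.character(unlist(b$protein_ids))
  b$biomarkers <- as.character(unlist(b$biomarkers))
  theta <- do.call(cbind, lapply(b$biomarkers,
                                 function(bm) unlist(b$theta[[bm]])))
  dimnames(theta) <- list(ids, b$biomarkers)
  beta <- if (is.null(b$beta)) NULL else
    do.call(cbind, lapply(b$biomarkers, function(bm) unlist(b$beta[[bm]])))
  ctl_args <- b$control[intersect(names(b$control),
                                  c("optimizer", "eta", "delta", "max_epochs",
                                    "tol", "theta_init", "init_sd", "phi_min",
                                    "clip"))]
  ctl <- do.call(gpnet_control, lapply(ctl_args, unlist))
  structure(list(
    phi = stats::setNames(unlist(b$phi), ids), theta = theta, beta = beta,
    covariate_center = unlist(b$covariate_center),
    covariate_scale = unlist(b$covariate_scale),
    biomarkers = b$biomarkers, protein_ids = ids, sample_ids = NULL,
    network = network, delta = b$delta, loss_trace = unlist(b$loss_trace),
    epochs = b$epochs, converged = b$converged,
    fitted = NULL, synergy = NULL, labels = NULL,
    control = ctl, call = quote(read_gpnet())
  ), class = "gpnet")
}

detect_sep <- function(path) {
  line <- readLines(path, n = 1)
  if (lengths(regmatches(line, gregexpr("\t", line))) >=
      lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))) "\t"
  else ","
}
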