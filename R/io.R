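# Plain-text serialization: CSV containers for the standard inputs (long
# volume tables, covariates) and the package's own objects (adjacency sets
# as upper-triangle edge lists, embeddings as h/lam matrices).

#' Read a long-format volume table
#'
#' Expects columns `subject_id`, `visit_month`, `structure`, `volume_mm3`;
#' empty cells become `NA` (missing volumes, to be forward filled).
#'
#' @param path CSV file path.
#' @return Data frame ready for [forward_fill_volumes()].
#' @export
read_volume_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit_month", "structure", "volume_mm3")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("%s lacks column(s): %s", path, paste(miss, collapse = ", "))
  tab
}

#' Read a covariate table
#'
#' Expects columns `subject_id`, `age_years`, `icv_mm3`, `apoe_copies`,
#' `cdr`.
#'
#' @param path CSV file path.
#' @return Data frame of covariates.
#' @export
read_covariate_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_years", "icv_mm3", "apoe_copies", "cdr")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("%s lacks column(s): %s", path, paste(miss, collapse = ", "))
  tab
}

#' Write / read an adjacency set as a plain-text container
#'
#' `write_adjacency_set()` stores a structures manifest (`structures.txt`), a
#' subjects manifest (`subjects.txt`), and an upper-triangle edge list
#' (`edges.csv`: subject index, row, col of each present edge);
#' `read_adjacency_set()` reconstructs the binary matrices.
#'
#' @param A An `adjacency_set`.
#' @param dir Output directory (created if needed).
#' @return `write_adjacency_set()` returns `dir` invisibly;
#'   `read_adjacency_set()` returns the `adjacency_set`.
#' @export
write_adjacency_set <- function(A, dir) {
  stopifnot(inherits(A, "adjacency_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(A$structures, file.path(dir, "structures.txt"))
  m <- dim(A$matrices)[3L]
  ids <- A$subject_ids %||% sprintf("subject_%04d", seq_len(m))
  writeLines(ids, file.path(dir, "subjects.txt"))
  edges <- do.call(rbind, lapply(seq_len(m), function(s) {
    a <- A$matrices[, , s]
    ij <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
    if (nrow(ij)) data.frame(subject = s, row = ij[, 1L], col = ij[, 2L])
  }))
  utils::write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_adjacency_set
#' @export
read_adjacency_set <- function(dir) {
  structures <- readLines(file.path(dir, "structures.txt"))
  ids <- readLines(file.path(dir, "subjects.txt"))
  edges <- utils::read.csv(file.path(dir, "edges.csv"))
  n <- length(structures)
  m <- length(ids)
  A <- array(0, c(n, n, m))
  for (s in seq_len(m)) {
    a <- diag(n)
    e <- edges[edges$subject == s, , drop = FALSE]
    a[cbind(e$row, e$col)] <- 1
    a[cbind(e$col, e$row)] <- 1
    A[, , s] <- a
  }
  adjacency_set(A, structures, ids)
}

#' Write / read an embedding as CSV
#'
#' Stores `h.csv` (structures x networks, with structure names) and
#' `lam.csv` (subjects x networks).
#'
#' @param emb An `mreg_embedding`.
#' @param dir Output directory (created if needed).
#' @return `write_embedding()` returns `dir` invisibly; `read_embedding()`
#'   returns the `mreg_embedding`.
#' @export
write_embedding <- function(emb, dir) {
  stopifnot(inherits(emb, "mreg_embedding"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- data.frame(structure = emb$structures, emb$h)
  colnames(h) <- c("structure", sprintf("network_%d", seq_len(emb$d)))
  utils::write.csv(h, file.path(dir, "h.csv"), row.names = FALSE)
  lam <- as.data.frame(emb$lam)
  colnames(lam) <- sprintf("network_%d", seq_len(emb$d))
  utils::write.csv(lam, file.path(dir, "lam.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(dir) {
  h <- utils::read.csv(file.path(dir, "h.csv"))
  lam <- utils::read.csv(file.path(dir, "lam.csv"))
  mreg_embedding(unname(as.matrix(h[, -1L, drop = FALSE])),
                 unname(as.matrix(lam)), structures = h$structure)
}
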