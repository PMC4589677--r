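# Internal helpers: atom-key parsing, small vector algebra, TSV output.

`%||%` <- function(a, b) if (is.null(a)) b else a

# "A:116:NE2" -> list(chain = "A", resid = 116L, name = "NE2")
parseAtomKey <- function(key) {
  if (is.list(key) && all(c("chain", "resid", "name") %in% names(key)))
    return(list(chain = as.character(key$chain),
                resid = as.integer(key$resid),
                name = as.character(key$name)))
  parts <- strsplit(as.character(key), ":", fixed = TRUE)[[1L]]
  if (length(parts) != 3L)
    stop("atom key must be 'chain:resid:atom', got: ", key, call. = FALSE)
  resid <- suppressWarnings(as.integer(parts[2L]))
  if (is.na(resid))
    stop("atom key has non-integer residue index: ", key, call. = FALSE)
  list(chain = parts[1L], resid = resid, name = parts[3L])
}

formatAtomKey <- function(k) paste(k$chain, k$resid, k$name, sep = ":")

# "120-132" or c(120, 132) -> integer(2)
parseResidueRange <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(x, "-", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("residue range must be 'first-last', got: ", x, call. = FALSE)
    x <- as.integer(parts)
  }
  x <- as.integer(x)
  if (length(x) != 2L || anyNA(x))
    stop("residue range must be two integers", call. = FALSE)
  x
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unitVector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

# Rotation by angle (radians) about a unit axis, Rodrigues form.
rotationAboutAxis <- function(axis, theta) {
  u <- unitVector(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Residue keys "chain:resid" in topology order of first appearance.
residueTable <- function(topology, indices = NULL) {
  a <- topology@atoms
  if (!is.null(indices)) a <- a[indices, , drop = FALSE]
  key <- paste(a$chain, a$resid, sep = ":")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resid = a$resid[first],
             stringsAsFactors = FALSE)
}

#' Write a table as tab-separated values
#'
#' Plain TSV with a header row, no quoting, no row names; \code{NA} entries
#' are written as \code{NA}. Used for all tabular outputs (profiles,
#' occupancy tables, angle series, matrices).
#'
#' @param x a data.frame.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write a residue-by-residue matrix as TSV
#'
#' Dense layout with residue keys as the header row and first column;
#' masked entries are written as \code{NA}.
#'
#' @param x a [CorrelationMatrix-class] or [DifferenceMatrix-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeMatrixTSV <- function(x, path) {
  v <- matrixValues(x)
  df <- data.frame(key = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- df[[1L]]
  v
}
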