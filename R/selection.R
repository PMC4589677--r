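#' Build a declarative atom selection
#'
#' @param chains character vector of chain identifiers, or NULL for all.
#' @param residues inclusive residue range, as \code{c(first, last)} or a
#'   string \code{"first-last"}; NULL for all residues.
#' @param atoms character vector of atom names, or the alias
#'   \code{"backbone"} for \code{c("N","CA","C","O")}; NULL for all atoms.
#' @return an [AtomSelection-class].
#' @examples
#' atomSelection(chains = "A", residues = "120-132", atoms = "backbone")
#' @export
atomSelection <- function(chains = NULL, residues = NULL, atoms = NULL) {
  if (!is.null(atoms)) {
    atoms <- as.character(atoms)
    if (any(atoms == "backbone"))
      atoms <- unique(c(.BACKBONE, atoms[atoms != "backbone"]))
  }
  new("AtomSelection",
      chains = as.character(chains %||% character()),
      residueRange = if (is.null(residues)) integer()
                     else parseResidueRange(residues),
      atomNames = atoms %||% character())
}

#' Resolve a selection against a topology
#'
#' Returns the 1-based indices of the selected atoms, in topology order.
#' Resolution is a pure function of (topology, selection) and is
#' deterministic. An empty result is an error naming the criterion that
#' failed to match.
#'
#' @param topology a [Topology-class].
#' @param selection an [AtomSelection-class] (or a [HelixDefinition-class],
#'   which selects its chain/range/atom-name triple).
#' @return integer vector of atom indices, ordered by topology order.
#' @export
resolveSelection <- function(topology, selection) {
  if (is(selection, "HelixDefinition"))
    selection <- new("AtomSelection", chains = selection@chain,
                     residueRange = selection@residueRange,
                     atomNames = selection@atomNames)
  stopifnot(is(topology, "Topology"), is(selection, "AtomSelection"))
  a <- topology@atoms
  ok <- rep(TRUE, nrow(a))
  crit <- character()
  if (length(selection@chains)) {
    m <- a$chain %in% selection@chains
    if (!any(m))
      crit <- c(crit, paste0("chains {",
                             paste(selection@chains, collapse = ","), "}"))
    ok <- ok & m
  }
  if (length(selection@residueRange)) {
    rr <- selection@residueRange
    m <- a$resid >= rr[1] & a$resid <= rr[2]
    if (!any(m)) crit <- c(crit, sprintf("residues %d-%d", rr[1], rr[2]))
    ok <- ok & m
  }
  if (length(selection@atomNames)) {
    m <- a$name %in% selection@atomNames
    if (!any(m))
      crit <- c(crit, paste0("atom names {",
                             paste(selection@atomNames, collapse = ","), "}"))
    ok <- ok & m
  }
  idx <- which(ok)
  if (length(idx) == 0L) {
    if (length(crit) == 0L) crit <- "the combination of criteria"
    stop("selection matched no atoms: ", paste(crit, collapse = " and "),
         call. = FALSE)
  }
  idx
}

#' Look up a single atom by key
#'
#' @param topology a [Topology-class].
#' @param key atom key string \code{"chain:resid:atom"} (e.g.
#'   \code{"A:116:NE2"}) or an equivalent list.
#' @return integer(1) atom index.
#' @export
atomIndex <- function(topology, key) {
  k <- parseAtomKey(key)
  a <- topology@atoms
  i <- which(a$chain == k$chain & a$resid == k$resid & a$name == k$name)
  if (length(i) != 1L)
    stop("atom not found in topology: ", formatAtomKey(k), call. = FALSE)
  i
}
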