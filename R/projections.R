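#' Projection catalog: which parameters are reducible, and to what values
#'
#' Out of the model's `d` parameters, a subset of `d_tilde` parameters is
#' declared *reducible*: each can be projected to a fixed projection value
#' (0 for a multiplicative kinetic constant deletes its reaction; a large
#' finite surrogate stands in for "project to infinity", e.g. to remove a
#' saturable step).  Asymmetric couplings declare that projecting one
#' parameter drags others with it -- the classic case being a
#' Michaelis-Menten constant that is eliminated together with its catalytic
#' constant, but not vice versa.  Coupling targets must themselves be
#' reducible, and the closure used throughout the package is transitive.
#'
#' @param parameter_names all model parameter names (fixes index order).
#' @param reducible character vector of reducible parameter names.
#' @param projection_values named numeric vector, one value per reducible
#'   parameter (default 0 for every reducible parameter).
#' @param couplings named list: `couplings[["a"]] = c("b", "c")` means
#'   projecting `a` additionally projects `b` and `c`.
#' @return an object of class `"projection_catalog"`.
#' @export
projection_catalog <- function(parameter_names, reducible,
                               projection_values = NULL, couplings = NULL) {
  stopifnot(is.character(parameter_names), is.character(reducible))
  if (!all(reducible %in% parameter_names)) {
    stop("reducible parameters must be declared model parameters", call. = FALSE)
  }
  if (anyDuplicated(reducible)) stop("duplicate reducible parameters", call. = FALSE)
  if (is.null(projection_values)) {
    projection_values <- stats::setNames(rep(0, length(reducible)), reducible)
  }
  if (is.null(names(projection_values)) || !setequal(names(projection_values), reducible)) {
    stop("projection_values must be named, one per reducible parameter", call. = FALSE)
  }
  projection_values <- projection_values[reducible]
  if (any(!is.finite(projection_values))) {
    stop("projection values must be finite (use a large finite surrogate for 'project to infinity')",
         call. = FALSE)
  }
  couplings <- couplings %||% list()
  for (src in names(couplings)) {
    if (!src %in% reducible) {
      stop(sprintf("coupling source '%s' is not a reducible parameter", src), call. = FALSE)
    }
    tgt <- couplings[[src]]
    if (!all(tgt %in% parameter_names)) {
      bad <- setdiff(tgt, parameter_names)
      stop(sprintf("coupling target '%s' is not a declared parameter", bad[1]), call. = FALSE)
    }
    if (!all(tgt %in% reducible)) {
      bad <- setdiff(tgt, reducible)
      stop(sprintf("coupling target '%s' must be reducible (it needs a projection value)", bad[1]),
           call. = FALSE)
    }
  }
  structure(list(parameter_names = parameter_names,
                 reducible = reducible,
                 reducible_idx = match(reducible, parameter_names),
                 projection_values = projection_values,
                 couplings = couplings),
            class = "projection_catalog")
}

#' Transitive coupling closure of an index set
#'
#' Expands a set of reducible-parameter indices by the catalog's asymmetric
#' couplings until it is closed.  Idempotent; the empty map is the identity.
#'
#' @param catalog a [projection_catalog()].
#' @param I integer vector of parameter indices (positions in
#'   `parameter_names`) or character vector of parameter names.
#' @return sorted integer vector of indices, closed under couplings.
#' @export
close_couplings <- function(catalog, I) {
  stopifnot(inherits(catalog, "projection_catalog"))
  if (is.character(I)) I <- match(I, catalog$parameter_names)
  I <- as.integer(I)
  if (anyNA(I)) stop("unknown parameter in index set", call. = FALSE)
  if (!all(I %in% catalog$reducible_idx)) {
    stop("index set must be a subset of the reducible set", call. = FALSE)
  }
  if (length(catalog$couplings) == 0L || length(I) == 0L) return(sort(unique(I)))
  nm <- catalog$parameter_names
  seen <- unique(I)
  queue <- seen
  while (length(queue) > 0L) {
    i <- queue[[1L]]; queue <- queue[-1L]
    tgt <- catalog$couplings[[nm[i]]]
    if (!is.null(tgt)) {
      ti <- match(tgt, nm)
      new <- setdiff(ti, seen)
      if (length(new) > 0L) {
        seen <- c(seen, new)
        queue <- c(queue, new)
      }
    }
  }
  sort(unique(as.integer(seen)))
}

#' Reduction specification
#'
#' A candidate submodel, identified by the coupling-closed set `I` of
#' reducible parameters it projects.  The rank is the number of parameters
#' projected *relative to the parent* submodel; equal index sets compare
#' equal regardless of how they were discovered.
#'
#' @param catalog a [projection_catalog()].
#' @param I indices or names of parameters to project (need not be closed;
#'   closure is applied and the closed set is stored).
#' @param parent optional parent `reduction` this one extends.
#' @return an object of class `"reduction"` with fields `index_set`
#'   (sorted, closed), `names`, `rank`, `parent_id`, `id`.
#' @export
reduction <- function(catalog, I = integer(0), parent = NULL) {
  idx <- close_couplings(catalog, I)
  parent_idx <- if (is.null(parent)) integer(0) else parent$index_set
  if (!all(parent_idx %in% idx)) {
    stop("a reduction must contain its parent's index set", call. = FALSE)
  }
  nms <- catalog$parameter_names[idx]
  structure(list(index_set = idx,
                 names = nms,
                 rank = length(idx) - length(parent_idx),
                 parent_id = if (is.null(parent)) NA_character_ else parent$id,
                 id = tf_reduction_id(nms)),
            class = "reduction")
}

tf_reduction_id <- function(nms) {
  if (length(nms) == 0L) "(root)" else paste(nms, collapse = "+")
}

#' @export
print.reduction <- function(x, ...) {
  cat(sprintf("reduction %s (rank %d)\n", x$id, x$rank))
  invisible(x)
}

#' Apply a reduction to a parameter vector
#'
#' Sets every projected coordinate to its catalog projection value, exactly
#' (bitwise), and leaves all other coordinates unchanged.  Total and
#' idempotent.
#'
#' @param p named numeric parameter vector.
#' @param red a [reduction()].
#' @param catalog the [projection_catalog()].
#' @return the projected parameter vector.
#' @export
apply_reduction <- function(p, red, catalog) {
  stopifnot(inherits(red, "reduction"), inherits(catalog, "projection_catalog"))
  if (length(red$index_set) == 0L) return(p)
  if (is.null(names(p))) names(p) <- catalog$parameter_names
  p[catalog$parameter_names[red$index_set]] <-
    catalog$projection_values[catalog$parameter_names[red$index_set]]
  p
}

#' Enumerate candidate reductions up to a given rank
#'
#' All subsets of size `1..max_rank` of the parent's remaining reducible
#' set, each closed under couplings, de-duplicated after closure, in the
#' deterministic order "by subset size, then lexicographic on sorted
#' indices" so that runs are reproducible.  A `max_rank` beyond the
#' remaining number of reducible parameters is silently capped.
#'
#' @param catalog a [projection_catalog()].
#' @param parent the [reduction()] being extended (the search root).
#' @param max_rank highest number of additional parameters to project
#'   simultaneously (the exhaustive-search rank `r >= 1`).
#' @return list of [reduction()] objects (each strictly extends `parent`).
#' @export
enumerate_reductions <- function(catalog, parent, max_rank) {
  stopifnot(max_rank >= 1)
  remaining <- setdiff(catalog$reducible_idx, parent$index_set)
  remaining <- sort(remaining)
  r <- min(max_rank, length(remaining))
  out <- list()
  seen <- character(0)
  for (size in seq_len(r)) {
    # combn(x, ...) with scalar x would expand to seq_len(x)
    combos <- if (length(remaining) == 1L) list(remaining) else
      utils::combn(remaining, size, simplify = FALSE)
    for (A in combos) {
      red <- reduction(catalog, c(parent$index_set, A), parent = parent)
      if (!red$id %in% seen) {
        seen <- c(seen, red$id)
        out[[length(out) + 1L]] <- red
      }
    }
  }
  out
}
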