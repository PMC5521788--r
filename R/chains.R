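#' Define a radionuclide
#'
#' A nuclide carries its physical half-life and the derived decay constant
#' \eqn{\lambda = \ln 2 / T_{1/2}}. All times are in seconds internally;
#' unit conversion happens at the call boundary.
#'
#' @param name Nuclide identifier, e.g. `"Bi-213"`.
#' @param half_life_s Physical half-life in seconds (> 0).
#' @return An object of class `nuclide` with fields `name`, `half_life`
#'   (s) and `lambda` (s^-1).
#' @examples
#' bi <- nuclide("Bi-213", 45.59 * 60)
#' bi$lambda * bi$half_life  # ln 2
#' @export
nuclide <- function(name, half_life_s) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_s) || length(half_life_s) != 1L ||
      !is.finite(half_life_s) || half_life_s <= 0) {
    stop("half_life_s must be a single positive finite number", call. = FALSE)
  }
  structure(
    list(name = name, half_life = half_life_s, lambda = log(2) / half_life_s),
    class = "nuclide"
  )
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s: T1/2 = %g s, lambda = %g s^-1\n",
              x$name, x$half_life, x$lambda))
  invisible(x)
}

#' Assemble a decay chain
#'
#' A decay chain is a rooted, acyclic set of nuclides connected by decay
#' edges with branching ratios. The chain used throughout this package is
#' the Bi-213 two-branch chain
#' Bi-213 -> Po-213 (97.84%) / Tl-209 (2.16%) -> Pb-209; a single nuclide
#' (e.g. Lu-177) is the degenerate one-member chain.
#'
#' @param nuclides List of [nuclide()] objects (unique names).
#' @param edges Data frame with columns `parent`, `daughter`,
#'   `branching_ratio`; may have zero rows for a single-member chain.
#' @return An object of class `decay_chain`.
#' @seealso [bi213_chain()], [lu177_chain()], [read_chain()]
#' @export
decay_chain <- function(nuclides, edges = NULL) {
  if (inherits(nuclides, "nuclide")) nuclides <- list(nuclides)
  stopifnot(is.list(nuclides), all(vapply(nuclides, inherits, TRUE, "nuclide")))
  nms <- vapply(nuclides, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate nuclide names in chain", call. = FALSE)
  names(nuclides) <- nms

  if (is.null(edges)) {
    edges <- data.frame(parent = character(), daughter = character(),
                        branching_ratio = numeric())
  }
  stopifnot(all(c("parent", "daughter", "branching_ratio") %in% names(edges)))
  if (nrow(edges) > 0) {
    if (!all(edges$parent %in% nms) || !all(edges$daughter %in% nms)) {
      stop("edge refers to a nuclide not in the chain", call. = FALSE)
    }
    if (any(edges$branching_ratio < 0 | edges$branching_ratio > 1)) {
      stop("branching ratios must lie in [0, 1]", call. = FALSE)
    }
    br_out <- tapply(edges$branching_ratio, edges$parent, sum)
    if (any(br_out > 1 + 1e-9)) {
      stop("outgoing branching ratios from a nuclide exceed 1", call. = FALSE)
    }
  }

  roots <- setdiff(nms, edges$daughter)
  if (length(roots) != 1L) {
    stop("chain must have exactly one root (parent) nuclide", call. = FALSE)
  }

  chain <- structure(
    list(nuclides = nuclides, edges = edges, root = roots),
    class = "decay_chain"
  )
  # acyclicity: every node must be reachable from the root in finite steps
  paths <- chain_paths(chain)
  if (!setequal(names(paths), nms)) {
    stop("chain is cyclic or disconnected", call. = FALSE)
  }
  chain
}

#' @export
print.decay_chain <- function(x, ...) {
  cat(sprintf("<decay_chain> root %s, %d nuclide(s)\n",
              x$root, length(x$nuclides)))
  if (nrow(x$edges) > 0) {
    for (i in seq_len(nrow(x$edges))) {
      cat(sprintf("  %s -> %s (BR %.4f)\n", x$edges$parent[i],
                  x$edges$daughter[i], x$edges$branching_ratio[i]))
    }
  }
  invisible(x)
}

# Enumerate all root->node decay paths. Returns a named list (one entry
# per reachable nuclide) of lists with fields `names`, `lambdas`, `br`
# (product of edge branching ratios along the path). A nuclide fed by two
# branches (Pb-209) gets one entry per path. Errors out on cycles via
# depth cap.
chain_paths <- function(chain) {
  out <- list()
  n_max <- length(chain$nuclides) + 1L
  walk <- function(name, path_names, path_lambdas, br) {
    if (length(path_names) > n_max) stop("cycle detected in chain", call. = FALSE)
    nuc <- chain$nuclides[[name]]
    path_names <- c(path_names, name)
    path_lambdas <- c(path_lambdas, nuc$lambda)
    out[[name]] <<- c(out[[name]], list(
      list(names = path_names, lambdas = path_lambdas, br = br)))
    kids <- chain$edges[chain$edges$parent == name, , drop = FALSE]
    for (i in seq_len(nrow(kids))) {
      walk(kids$daughter[i], path_names, path_lambdas,
           br * kids$branching_ratio[i])
    }
  }
  walk(chain$root, character(), numeric(), 1)
  out
}

#' Cumulative branching fraction to each chain member
#'
#' The fraction of parent decays that eventually pass through each
#' nuclide (sum of branching-ratio products over all feeding paths).
#' For the Bi-213 chain this is 1 for Bi-213 and Pb-209, 0.9784 for
#' Po-213 and 0.0216 for Tl-209.
#'
#' @param chain A [decay_chain()].
#' @return Named numeric vector in chain order.
#' @export
branching_fraction <- function(chain) {
  stopifnot(inherits(chain, "decay_chain"))
  paths <- chain_paths(chain)
  vapply(paths, function(pl) sum(vapply(pl, `[[`, 0, "br")), 0)
}

#' Read a decay chain from a CSV specification
#'
#' Expects columns `nuclide`, `half_life_s`, `parent`, `branching_ratio`.
#' The root row leaves `parent` (and `branching_ratio`) empty. A nuclide
#' with two parents (Pb-209) appears on two rows with identical
#' `half_life_s`.
#'
#' @param path Path to the CSV file.
#' @return A [decay_chain()].
#' @export
read_chain <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nuclide", "half_life_s", "parent", "branching_ratio")
  if (!all(need %in% names(df))) {
    stop("chain CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  hl <- tapply(df$half_life_s, df$nuclide, unique)
  if (any(lengths(hl) != 1)) {
    stop("inconsistent half_life_s for a repeated nuclide", call. = FALSE)
  }
  nucs <- lapply(names(hl), function(nm) nuclide(nm, hl[[nm]]))
  has_parent <- !is.na(df$parent) & nzchar(df$parent)
  edges <- data.frame(
    parent = df$parent[has_parent],
    daughter = df$nuclide[has_parent],
    branching_ratio = as.numeric(df$branching_ratio[has_parent])
  )
  decay_chain(nucs, edges)
}

#' Packaged Bi-213 decay chain
#'
#' Bi-213 (T1/2 45.59 min) decays to Po-213 (4.2 us, BR 0.9784) and
#' Tl-209 (2.16 min, BR 0.0216), both feeding Pb-209 (3.253 h). Pb-209's
#' daughter Bi-209 is effectively stable and carries no dose, so the
#' chain ends there.
#'
#' @return A [decay_chain()].
#' @export
bi213_chain <- function() {
  read_chain(system.file("extdata", "bi213_chain.csv", package = "cellrad",
                         mustWork = TRUE))
}

#' Packaged Lu-177 single-nuclide chain
#'
#' Lu-177, T1/2 = 6.647 d, treated as a chain of one (its daughter
#' Hf-177 is stable).
#'
#' @return A [decay_chain()].
#' @export
lu177_chain <- function() {
  read_chain(system.file("extdata", "lu177_chain.csv", package = "cellrad",
                         mustWork = TRUE))
}
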