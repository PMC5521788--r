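#' Read a cellular S-value set
#'
#' Loads MIRD-schema cellular S-values (mGy/MBq.s) for a fixed cell
#' geometry: self-dose from activity distributed in the cell
#' S(C<-C), from activity on the cell surface S(C<-CS), and cross-dose
#' from a neighbouring cell at tabulated centre distances. The packaged
#' fixture (`cell_s_values_6um.csv`) holds per-nuclide values for a
#' 6-um-radius spherical cell for the Bi-213 chain members and Lu-177.
#' The sentinel `OOR` marks a cross-dose entry beyond the emission range
#' (read as `NA`).
#'
#' @param path CSV with header
#'   `nuclide,s_self,s_surface,s_cross_50um,s_cross_100um`.
#' @param cell_radius_um Cell radius the values were computed for
#'   (metadata only; default 6).
#' @return Data frame of class `cell_s_table` with attribute
#'   `cell_radius_um` and cross-distance columns discoverable via
#'   attribute `cross_distances_um`.
#' @export
read_cell_s_values <- function(path, cell_radius_um = 6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "OOR"))
  need <- c("nuclide", "s_self", "s_surface")
  if (!all(need %in% names(df))) {
    stop("cell S-value CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  cross_cols <- grep("^s_cross_\\d+um$", names(df), value = TRUE)
  for (cc in c("s_self", "s_surface", cross_cols)) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  if (any(df$s_self < df$s_surface, na.rm = TRUE)) {
    stop("self-dose S must be >= surface S for every nuclide", call. = FALSE)
  }
  if (any(df$s_self <= 0 | df$s_surface <= 0, na.rm = TRUE)) {
    stop("self and surface S-values must be positive", call. = FALSE)
  }
  attr(df, "cell_radius_um") <- cell_radius_um
  attr(df, "cross_distances_um") <-
    as.numeric(sub("^s_cross_(\\d+)um$", "\\1", cross_cols))
  class(df) <- c("cell_s_table", class(df))
  df
}

#' Packaged cellular S-values (6 um cell radius)
#' @return A `cell_s_table` covering Bi-213, Po-213, Tl-209, Pb-209 and
#'   Lu-177.
#' @export
cell_s_values_6um <- function() {
  read_cell_s_values(system.file("extdata", "cell_s_values_6um.csv",
                                 package = "cellrad", mustWork = TRUE))
}

#' Branching-weighted combined S-value for a decay chain
#'
#' Effective cellular S-value per parent decay: each member's S-value
#' weighted by the cumulative branching fraction of parent decays that
#' reach it, \eqn{S_{eff} = \sum_i BF_i S_i}. For the Bi-213 chain with
#' the packaged 6-um self-dose values this reproduces the combined
#' "parent + progeny" self-dose S of 50.2 mGy/MBq.s.
#'
#' @param svals A `cell_s_table` (see [read_cell_s_values()]).
#' @param chain A [decay_chain()].
#' @param site `"self"` (activity in the cell) or `"surface"` (activity
#'   on the membrane).
#' @return Effective S in mGy/MBq.s per parent decay.
#' @examples
#' combine_chain_s(cell_s_values_6um(), bi213_chain(), "self")     # 50.2
#' combine_chain_s(cell_s_values_6um(), bi213_chain(), "surface")  # 33.7
#' @export
combine_chain_s <- function(svals, chain, site = c("self", "surface")) {
  site <- match.arg(site)
  stopifnot(inherits(svals, "cell_s_table"), inherits(chain, "decay_chain"))
  bf <- branching_fraction(chain)
  missing <- setdiff(names(bf), svals$nuclide)
  if (length(missing)) {
    stop("no cellular S-values for chain member(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  col <- if (site == "self") "s_self" else "s_surface"
  s <- svals[[col]][match(names(bf), svals$nuclide)]
  sum(bf * s)
}

#' Mean self-absorbed dose to a cell from specifically bound activity
#'
#' Absorbed dose to a single cell from radioligand bound to it,
#' integrated over the colony-formation period: per chain member,
#' \deqn{\bar{D} = \tilde{A}\,[f_{int} S(C\leftarrow C) +
#'   f_{mem} S(C\leftarrow CS)] \times 10^{-3}\ \mathrm{Gy},}
#' with \eqn{\tilde{A}} the member's cumulated activity over the window.
#' `A_cell` is the measured bound parent activity at the start of the
#' window `T0` (the end of the incubation); internally it is referred
#' back to the t = 0 Bateman reference (daughters zero at t = 0), so
#' daughter in-growth during the incubation is carried into the window.
#' No clearance of bound ligand is assumed.
#'
#' @param A_cell Bound parent activity per cell at `window[1]`, MBq.
#' @param chain A [decay_chain()].
#' @param f_int,f_mem Internalised and membrane-bound fractions of the
#'   bound activity; must be non-negative and sum to 1 (or both 0 for
#'   the degenerate no-binding case).
#' @param svals A `cell_s_table`.
#' @param window `(T0, T)` in seconds; default 1 h to 12 d.
#' @return A `dose_breakdown` (components by nuclide; radiation classes
#'   are not resolved by cellular S-values, labelled `"all"`).
#' @export
cell_mean_dose <- function(A_cell, chain, f_int = 0, f_mem = 1, svals,
                           window = c(3600, 12 * 86400)) {
  stopifnot(inherits(chain, "decay_chain"), inherits(svals, "cell_s_table"),
            length(window) == 2L)
  check_activity(A_cell)
  if (f_int < 0 || f_mem < 0) {
    stop("binding fractions must be non-negative", call. = FALSE)
  }
  if (f_int + f_mem > 0 && abs(f_int + f_mem - 1) > 1e-9) {
    stop("f_int + f_mem must equal 1 (bound-activity partition)",
         call. = FALSE)
  }
  lam <- chain$nuclides[[chain$root]]$lambda
  A0 <- A_cell * exp(lam * window[1])  # t = 0 reference of the Bateman forms
  ca <- cumulated_activity_chain(A0, chain, window[1], window[2])
  idx <- match(names(ca$per_nuclide), svals$nuclide)
  if (anyNA(idx)) {
    stop("no cellular S-values for chain member(s): ",
         paste(names(ca$per_nuclide)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  s_eff <- f_int * svals$s_self[idx] + f_mem * svals$s_surface[idx]
  comp <- data.frame(
    nuclide = names(ca$per_nuclide),
    radiation_class = "all",
    dose_Gy = unname(ca$per_nuclide * s_eff * 1e-3)
  )
  dose_breakdown(comp, cumulated = ca)
}

#' Upper bound on cross-dose from a neighbouring cell
#'
#' Dose to a cell from activity in another cell at a given centre
#' distance, using the tabulated cross-dose S-value at the nearest
#' tabulated distance not exceeding `distance_um`. Beyond the largest
#' tabulated distance (or where the table marks the entry out of range)
#' the bound is 0 and the result is flagged `out_of_range`.
#'
#' @param svals A `cell_s_table`.
#' @param nuclide_name Nuclide to look up.
#' @param distance_um Centre-to-centre distance in um.
#' @param A_tilde Cumulated activity in the source cell, MBq.s.
#' @return List with `dose_Gy` and logical `out_of_range`.
#' @export
cross_dose_bound <- function(svals, nuclide_name, distance_um, A_tilde) {
  stopifnot(inherits(svals, "cell_s_table"))
  check_activity(A_tilde)
  row <- match(nuclide_name, svals$nuclide)
  if (is.na(row)) stop("unknown nuclide: ", nuclide_name, call. = FALSE)
  dists <- sort(attr(svals, "cross_distances_um"))
  if (distance_um > max(dists)) {
    return(list(dose_Gy = 0, out_of_range = TRUE))
  }
  usable <- dists[dists <= distance_um]
  if (length(usable) == 0L) {
    stop("distance below the smallest tabulated cross-dose distance (",
         min(dists), " um)", call. = FALSE)
  }
  # cross S falls with distance, so the nearest tabulated distance not
  # exceeding the requested one gives an upper bound
  d_use <- usable[length(usable)]
  s <- svals[[sprintf("s_cross_%dum", d_use)]][row]
  if (is.na(s)) {
    return(list(dose_Gy = 0, out_of_range = TRUE))
  }
  list(dose_Gy = A_tilde * s * 1e-3, out_of_range = FALSE)
}
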