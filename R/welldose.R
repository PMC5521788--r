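#' Read a layer S-value table
#'
#' Loads absorbed fractions and dose-rate-per-activity coefficients
#' (S-values, mGy/MBq.s) for a dose-scoring layer of the 6-well-plate
#' geometry, broken down by nuclide and radiation class
#' (`alpha`, `beta`, `auger_ic`, `gamma`). The packaged fixture
#' (`layer_s_values_bi213.csv`) holds the bottom-25-um-layer values for
#' the Bi-213 chain from Monte Carlo transport of the 2 mL well medium;
#' user tables for other nuclides (e.g. Lu-177) use the same schema.
#'
#' @param path CSV with header
#'   `nuclide,radiation_class,phi,s_mGy_per_MBq_s`. Blank `phi`/S cells
#'   are read as 0. `phi` is the absorbed fraction of emitted energy
#'   (dimensionless, in `[0, 1]`).
#' @return Data frame of class `layer_s_table`.
#' @export
read_layer_s_values <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nuclide", "radiation_class", "phi", "s_mGy_per_MBq_s")
  if (nrow(df) == 0L) stop("empty S-value table: ", path, call. = FALSE)
  if (!all(need %in% names(df))) {
    stop("layer S-value CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df$phi[is.na(df$phi)] <- 0
  df$s_mGy_per_MBq_s[is.na(df$s_mGy_per_MBq_s)] <- 0
  bad_phi <- which(df$phi < 0 | df$phi > 1)
  if (length(bad_phi)) {
    stop("absorbed fraction phi outside [0, 1] at row ", bad_phi[1],
         call. = FALSE)
  }
  bad_s <- which(df$s_mGy_per_MBq_s < 0)
  if (length(bad_s)) {
    stop("negative S-value at row ", bad_s[1], call. = FALSE)
  }
  known <- c("alpha", "beta", "auger_ic", "gamma")
  if (!all(df$radiation_class %in% known)) {
    stop("radiation_class must be one of: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("layer_s_table", class(df))
  df
}

#' Packaged bottom-layer S-values for the Bi-213 chain
#'
#' Absorbed dose rate per unit activity in the bottom 25 um layer of a
#' 6-well plate cavity filled with 2 mL of homogeneously radioactive
#' medium, per chain member and radiation class.
#' @return A `layer_s_table`.
#' @export
layer_s_values_bi213 <- function() {
  read_layer_s_values(system.file("extdata", "layer_s_values_bi213.csv",
                                  package = "cellrad", mustWork = TRUE))
}

#' Absorbed dose to the bottom cell layer from the incubation medium
#'
#' Mean absorbed dose delivered to cells lying on the well bottom by
#' radioactivity homogeneously distributed in the incubation medium:
#' per chain member and radiation class,
#' \eqn{D = \tilde{A} \times S \times 10^{-3}} Gy, with the cumulated
#' activity \eqn{\tilde{A}} (MBq.s) from the decay-chain closed forms
#' and S in mGy/MBq.s. No specific binding is involved; this is the
#' non-specific (medium) dose route.
#'
#' @param A0 Parent activity in the well at t = 0, MBq.
#' @param chain A [decay_chain()].
#' @param incubation Length-2 numeric, incubation window `(t0, t1)` in
#'   seconds (default 0 to 1 h).
#' @param table A `layer_s_table` (see [read_layer_s_values()]); must
#'   cover every chain member with nonzero cumulated activity and
#'   nonzero emissions.
#' @return Object of class `dose_breakdown`: data frame `components`
#'   (`nuclide`, `radiation_class`, `dose_Gy`), `total_Gy`, and
#'   `alpha_fraction` (share of the total delivered by alpha particles).
#' @examples
#' d <- medium_dose(1, bi213_chain(), c(0, 3600), layer_s_values_bi213())
#' d$total_Gy        # ~1.12 Gy per MBq
#' d$alpha_fraction  # ~0.96
#' @export
medium_dose <- function(A0, chain, incubation = c(0, 3600), table) {
  stopifnot(inherits(chain, "decay_chain"), inherits(table, "layer_s_table"),
            length(incubation) == 2L)
  ca <- cumulated_activity_chain(A0, chain, incubation[1], incubation[2])
  active <- names(ca$per_nuclide)[ca$per_nuclide > 0]
  missing <- setdiff(active, table$nuclide)
  if (length(missing)) {
    stop("no S-value rows for chain member(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  comp <- table[table$nuclide %in% names(ca$per_nuclide),
                c("nuclide", "radiation_class", "s_mGy_per_MBq_s")]
  comp$dose_Gy <- ca$per_nuclide[comp$nuclide] * comp$s_mGy_per_MBq_s * 1e-3
  comp <- comp[, c("nuclide", "radiation_class", "dose_Gy")]
  rownames(comp) <- NULL
  dose_breakdown(comp, cumulated = ca)
}

# Construct a dose_breakdown from a component table.
dose_breakdown <- function(components, cumulated = NULL) {
  total <- sum(components$dose_Gy)
  alpha <- sum(components$dose_Gy[components$radiation_class == "alpha"])
  structure(
    list(components = components,
         total_Gy = total,
         alpha_fraction = if (total > 0) alpha / total else 0,
         cumulated = cumulated),
    class = "dose_breakdown"
  )
}

#' @export
print.dose_breakdown <- function(x, ...) {
  cat("<dose_breakdown>\n")
  print(transform(x$components, dose_Gy = signif(dose_Gy, 4)))
  cat(sprintf("total: %.4g Gy (alpha fraction %.3f)\n",
              x$total_Gy, x$alpha_fraction))
  invisible(x)
}
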