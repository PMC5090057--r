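#' Neocortex ratio
#'
#' Dunbar's neocortex ratio: neocortex volume divided by the volume of the
#' rest of the brain.
#'
#' @param brain_volume Total brain volume (cm^3), > 0. Vectorized.
#' @param neocortex_volume Neocortex volume (cm^3), > 0 and smaller than
#'   `brain_volume`.
#' @return `neocortex_volume / (brain_volume - neocortex_volume)`.
#' @examples
#' compute_nr(1251.847, 1006.525)  # human, ~4.10
#' @export
compute_nr <- function(brain_volume, neocortex_volume) {
  if (length(brain_volume) != length(neocortex_volume))
    stop("volume vectors must have equal length", call. = FALSE)
  if (any(!is.finite(brain_volume)) || any(!is.finite(neocortex_volume)) ||
      any(brain_volume <= 0) || any(neocortex_volume <= 0))
    stop("volumes must be finite and positive", call. = FALSE)
  if (any(neocortex_volume >= brain_volume))
    stop("neocortex_volume must be smaller than brain_volume", call. = FALSE)
  neocortex_volume / (brain_volume - neocortex_volume)
}

#' Encephalization index
#'
#' Residual log brain mass after allometric body-size correction:
#' `log(brain_mass) - b * log(body_mass)`. The default slope b = 0.64 is the
#' published log-log regression estimate across 493 mammalian species and is
#' taken as a given constant.
#'
#' @param brain_mass Brain mass in grams, > 0. Vectorized.
#' @param body_mass Body mass in grams, > 0.
#' @param b Allometric slope (default 0.64).
#' @param base Logarithm base; natural log by default.
#' @return Encephalization index (dimensionless, log scale).
#' @export
compute_ei <- function(brain_mass, body_mass, b = 0.64, base = exp(1)) {
  if (any(!is.finite(brain_mass)) || any(!is.finite(body_mass)) ||
      any(brain_mass <= 0) || any(body_mass <= 0))
    stop("masses must be finite and positive", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 0)
    stop("'b' must be a single non-negative number", call. = FALSE)
  log(brain_mass, base = base) - b * log(body_mass, base = base)
}

#' Check tabulated neocortex ratios against volumes
#'
#' Recomputes the neocortex ratio from the stored volumes and flags each
#' species as `consistent` (|computed - tabulated| <= `tol`), `inconsistent`,
#' or `printed_only` (volumes unavailable, or the row is marked as carrying
#' a ratio transcribed from its source). Never mutates the table.
#'
#' @param table A `phenotype_table`.
#' @param tol Absolute tolerance (default 0.01, i.e. one unit in the second
#'   printed decimal).
#' @return A data.frame with columns `species`, `printed_nr`, `computed_nr`,
#'   `status`.
#' @export
validate_nr_consistency <- function(table, tol = 0.01) {
  n <- nrow(table)
  computed <- rep(NA_real_, n)
  status <- character(n)
  has_vol <- is.finite(table$brain_volume) & is.finite(table$neocortex_volume)
  for (i in seq_len(n)) {
    if (!has_vol[i]) {
      status[i] <- "printed_only"
      next
    }
    computed[i] <- compute_nr(table$brain_volume[i], table$neocortex_volume[i])
    status[i] <- if (abs(computed[i] - table$nr[i]) <= tol)
      "consistent" else "inconsistent"
  }
  data.frame(species = table$species, printed_nr = table$nr,
             computed_nr = computed, status = status,
             stringsAsFactors = FALSE)
}

#' Extract a species-aligned trait vector
#'
#' @param table A `phenotype_table`.
#' @param trait One of `"nr"`, `"ei"`, `"mlsp"`.
#' @param species Optional species ordering; defaults to table order.
#' @return Named numeric vector aligned to `species`.
#' @export
trait_vector <- function(table, trait = c("nr", "ei", "mlsp"),
                         species = NULL) {
  trait <- match.arg(trait)
  v <- setNames(table[[trait]], table$species)
  if (is.null(species)) return(v)
  missing <- setdiff(species, names(v))
  if (length(missing) > 0L)
    stop("species absent from phenotype table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  v[species]
}
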