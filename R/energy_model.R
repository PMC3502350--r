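#' Nearest-neighbor energy parameters for RNA folding
#'
#' Returns the packaged 37 degC free-energy parameter set used by
#' [fold_mfe()]: a 6x6 stacking table over the pair alphabet
#' \code{CG, GC, GU, UG, AU, UA} (kcal/mol; rows = outer pair 5'i-j3', columns
#' = inner pair), tabulated hairpin / bulge / internal-loop initiation
#' penalties for loop sizes 1..30 (Jacobson-Stockmayer logarithmic
#' extrapolation \code{1.75*RT*ln(size/30)} beyond), an internal-loop
#' asymmetry term, and affine multiloop coefficients.  This is a reduced
#' model: no dangles, no coaxial stacking, no tetraloop bonuses, no terminal
#' AU penalty, so absolute energies are not comparable to full Turner-model
#' folders; within the package the same table drives both the dynamic
#' program and the exhaustive test oracle.
#'
#' The stacking table satisfies the thermodynamic symmetry
#' \code{E(p1 over p2) == E(rev(p2) over rev(p1))}, where \code{rev} swaps
#' the two bases of a pair.
#'
#' @return List with elements \code{stack}, \code{hairpin}, \code{bulge},
#'   \code{internal}, \code{asym_coef}, \code{asym_max}, \code{ml_a},
#'   \code{ml_b}, \code{ml_c}, \code{max_interior}, \code{min_hairpin},
#'   \code{version}.
#' @export
rna_energy_params <- function() {
  pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  s <- function(p1, p2, e) {
    stack[p1, p2] <<- e
    # symmetric partner: reverse both pairs and swap roles
    rev2 <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
    stack[rev2(p2), rev2(p1)] <<- e
  }
  s("AU", "AU", -0.93); s("AU", "CG", -2.24); s("AU", "GC", -2.08)
  s("AU", "GU", -0.55); s("AU", "UA", -1.10); s("AU", "UG", -1.36)
  s("CG", "AU", -2.11); s("CG", "CG", -3.26); s("CG", "GC", -2.36)
  s("CG", "GU", -1.41); s("CG", "UG", -2.11)
  s("GC", "AU", -2.35); s("GC", "CG", -3.42); s("GC", "GU", -1.53)
  s("GU", "AU", -1.27); s("GU", "CG", -2.51); s("GU", "GU", -0.50)
  s("GU", "UG", 1.29)
  s("UA", "AU", -1.33); s("UA", "GU", -1.00); s("UA", "UA", -0.93)
  s("UG", "GU", 0.30); s("UG", "UG", -0.50)
  stopifnot(!anyNA(stack))

  RT <- 0.6163  # kcal/mol at 37 degC
  js <- function(base, from, n = 30) {
    # tabulated head, Jacobson-Stockmayer extension to size n
    sizes <- seq_along(base)
    out <- numeric(n)
    out[sizes] <- base
    if (n > length(base)) {
      k <- (length(base) + 1):n
      out[k] <- base[length(base)] + 1.75 * RT * log(k / length(base))
    }
    out
  }
  hairpin  <- js(c(NA, NA, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4))
  hairpin[1:2] <- 1e9  # loops below the 3-nt minimum are forbidden
  bulge    <- js(c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4))
  internal <- js(c(1e9, 1.5, 2.0, 2.5, 3.0, 3.5))  # minimum size 1+1

  list(stack = stack, hairpin = hairpin, bulge = bulge, internal = internal,
       asym_coef = 0.5, asym_max = 3.0,
       ml_a = 3.4, ml_b = 0.4, ml_c = 0.1,
       max_interior = 30L, min_hairpin = 3L,
       version = "1.0")
}
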