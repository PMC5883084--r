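#' Sample synthetic cis contacts with a known power-law exponent
#'
#' Draws contacts whose per-locus-pair probability scales as
#' `separation^alpha`, the reference behaviour of polymer globule models
#' (alpha -1.0 fractal, -1.5 equilibrium). Because the number of
#' available locus pairs at separation `s` on a chromosome of length `L`
#' is proportional to `L - s`, sampled separations follow a density
#' proportional to `(L - s) * s^alpha` (inverse-CDF draw from the pure
#' power law, thinned by `(L - s) / L`), so the pair-normalised
#' [contact_probability_curve()] recovers slope `alpha`.
#'
#' @param genome A [genome_assembly()].
#' @param n Number of contacts.
#' @param alpha Power-law exponent (negative).
#' @param seed Integer seed.
#' @param min_sep Smallest separation sampled (default 100 kb).
#' @return A contacts tibble (positions and chromosomes only, support 1).
#' @export
sample_powerlaw_contacts <- function(genome, n, alpha = -1.0, seed = 1,
                                     min_sep = 1e5) {
  chs <- genome$chromosomes
  n_per <- round(n * chs$length / sum(chs$length))
  draw_s <- function(k, lo, hi) {
    u <- stats::runif(k)
    if (abs(alpha + 1) < 1e-12) {
      lo * (hi / lo)^u
    } else {
      a1 <- alpha + 1
      (lo^a1 + u * (hi^a1 - lo^a1))^(1 / a1)
    }
  }
  with_seed_local(seed, {
    out <- purrr::map2_dfr(chs$name, seq_len(nrow(chs)), function(ch, i) {
      L <- chs$length[i]
      hi <- L - 1
      need <- n_per[i]
      seps <- numeric(0)
      while (length(seps) < need) {
        k <- max(1000, 2 * (need - length(seps)))
        s <- draw_s(k, min_sep, hi)
        keep <- stats::runif(k) < (L - s) / L
        seps <- c(seps, s[keep])
      }
      seps <- floor(seps[seq_len(need)])
      p1 <- floor(stats::runif(need) * (L - seps))
      tibble::tibble(chromA = ch, posA = p1, strandA = "+",
                     chromB = ch, posB = p1 + seps, strandB = "-",
                     support = 1L, cell_id = "powerlaw")
    })
    out
  })
}
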