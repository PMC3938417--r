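# Forward-time Wright-Fisher simulation of mtDNA haplotype frequencies
# through rodenticide-control demography: a constant-size control
# scenario (L), a bottleneck held after the introduction of
# anticoagulant control (M), and a bottleneck followed by population
# recovery driven by a resistance allele under balancing selection (R).

#' Specify a demographic scenario for the forward simulation
#'
#' The three scenarios share a neutrally drifting mtDNA pool founded
#' with `n_haplotypes` haplotypes, one focal haplotype at initial
#' frequency `i0` and the rest at equal shares of `1 - i0`:
#' \describe{
#'   \item{L}{constant effective size `Ne0` for all generations.}
#'   \item{M}{`Ne0` until generation `t1`, then an instant reduction to
#'     `Nei` (rodenticide mortality) held to the end.}
#'   \item{R}{as M, but a resistance allele at an unlinked autosomal
#'     locus appears at the bottleneck (frequency `p_R0`, a fraction
#'     `assoc0` of its copies in focal-haplotype individuals) under
#'     balancing selection; the census stays at `Nei` while resistance
#'     establishes (`t1` to `t2`) and then recovers to `Ne0` over the
#'     same number of generations.}
#' }
#' Defaults encode colonisation around 1750 with two generations per
#' year: 500 generations total, control beginning at generation 400
#' (about 1950) and resistance established within 10 years (20
#' generations). Selection is symmetric overdominance with coefficient
#' `s`: fitnesses (1-s, 1, 1-s) for (SS, RS, RR). The number of
#' transmitting mtDNA copies per generation is the female count, i.e.
#' half the census size, under the default `mt_copy_rule = "half"`.
#'
#' @param scenario `"L"`, `"M"` or `"R"`.
#' @param Ne0 baseline effective population size (default 10000).
#' @param Nei post-control effective size (default 100; the study grid
#'   is 100, 500, 3000, 7000).
#' @param generations total generations simulated (default 500).
#' @param t1 generation of rodenticide introduction (default 400).
#' @param t2 generation by which the population has recovered under
#'   scenario R (default 420).
#' @param n_haplotypes number of founding haplotypes (default 25).
#' @param i0 initial focal-haplotype frequency in (0, 1].
#' @param s balancing-selection coefficient (default 0.3).
#' @param w optional explicit fitness vector `c(SS=, RS=, RR=)`
#'   overriding `s`.
#' @param p_R0 resistance-allele frequency at `t1` (default 0.05).
#' @param assoc0 fraction of resistance copies initially carried by
#'   focal-haplotype individuals (default 1).
#' @param growth `"linear"` (constant census increment, default) or
#'   `"exponential"` recovery between `t1` and `t2`.
#' @param mt_copy_rule `"half"` (transmitting copies = Ne/2, default) or
#'   `"full"` (= Ne), a sensitivity switch.
#' @return an object of class `"demographic_model"`.
#' @export
demographic_model <- function(scenario = c("L", "M", "R"), Ne0 = 10000,
                              Nei = 100, generations = 500, t1 = 400,
                              t2 = 420, n_haplotypes = 25, i0 = 0.2,
                              s = 0.3, w = NULL, p_R0 = 0.05, assoc0 = 1,
                              growth = c("linear", "exponential"),
                              mt_copy_rule = c("half", "full")) {
  scenario <- match.arg(scenario)
  growth <- match.arg(growth)
  mt_copy_rule <- match.arg(mt_copy_rule)
  if (i0 <= 0 || i0 > 1) stop("i0 must be in (0, 1]")
  if (!(t1 < t2 && t2 <= generations))
    stop("need t1 < t2 <= generations")
  if (Nei > Ne0) stop("Nei must not exceed Ne0")
  if (p_R0 < 0 || p_R0 > 1 || assoc0 < 0 || assoc0 > 1)
    stop("p_R0 and assoc0 must lie in [0, 1]")
  if (is.null(w)) w <- c(SS = 1 - s, RS = 1, RR = 1 - s)
  if (!identical(names(w), c("SS", "RS", "RR")) || any(w < 0))
    stop("w must be a non-negative vector named SS, RS, RR")
  structure(list(scenario = scenario, Ne0 = as.integer(Ne0),
                 Nei = as.integer(Nei), generations = as.integer(generations),
                 t1 = as.integer(t1), t2 = as.integer(t2),
                 n_haplotypes = as.integer(n_haplotypes), i0 = i0,
                 s = s, w = w, p_R0 = p_R0, assoc0 = assoc0,
                 growth = growth, mt_copy_rule = mt_copy_rule),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  lab <- switch(x$scenario,
                L = "constant size",
                M = "bottleneck held",
                R = "bottleneck + recovery + resistance selection")
  cat(sprintf("Demographic model %s (%s)\n", x$scenario, lab))
  cat(sprintf("  Ne0 = %d, Nei = %d, generations = %d (t1 = %d, t2 = %d)\n",
              x$Ne0, x$Nei, x$generations, x$t1, x$t2))
  cat(sprintf("  %d haplotypes, focal i0 = %.3f, mtDNA copies = Ne%s\n",
              x$n_haplotypes, x$i0,
              if (x$mt_copy_rule == "half") "/2" else ""))
  if (x$scenario == "R")
    cat(sprintf("  selection w = (%.2f, %.2f, %.2f), p_R0 = %.3f, assoc0 = %.2f, %s recovery\n",
                x$w[1], x$w[2], x$w[3], x$p_R0, x$assoc0, x$growth))
  invisible(x)
}

#' Census-size trajectory of a model (internal)
#' @return integer vector of census sizes for generations 1..G.
#' @noRd
census_trajectory <- function(model) {
  G <- model$generations
  N <- rep(model$Ne0, G)
  if (model$scenario == "M") {
    N[(model$t1 + 1):G] <- model$Nei
  } else if (model$scenario == "R") {
    # suppressed at Nei while resistance establishes (t1..t2), then
    # recovery to Ne0 over the same number of generations
    N[(model$t1 + 1):model$t2] <- model$Nei
    ramp <- seq(model$t2 + 1L, min(model$t2 + (model$t2 - model$t1), G))
    if (model$growth == "linear") {
      N[ramp] <- round(seq(model$Nei, model$Ne0, length.out = length(ramp)))
    } else {
      N[ramp] <- round(exp(seq(log(model$Nei), log(model$Ne0),
                               length.out = length(ramp))))
    }
    if (max(ramp) < G) N[(max(ramp) + 1):G] <- model$Ne0
  }
  as.integer(N)
}

#' Transmitting mtDNA copies for a census size (internal)
#' @noRd
mt_copies <- function(N, rule) {
  m <- if (rule == "half") floor(N / 2) else N
  pmax(as.integer(m), 2L)
}

#' Forward-simulate mtDNA haplotype drift under a demographic model
#'
#' Per generation and replicate the population state is the joint count
#' vector over haplotype x resistance-genotype classes in the
#' transmitting (female) pool, plus genotype counts among males when the
#' resistance locus is active. Each generation applies viability
#' selection on genotypes (scenario R from `t1` on), random mating with
#' independent assortment of the autosomal locus, maternal transmission
#' of mtDNA, and multinomial resampling at the generation's census size.
#' Scenarios L and M carry no nuclear locus and reduce to neutral
#' multinomial drift of the haplotype counts.
#'
#' @param model a [demographic_model()].
#' @param replicates number of independent replicates (default 1000).
#' @param seed optional RNG seed (recorded in the result).
#' @param check verify count-conservation invariants every generation
#'   (small cost; mainly for tests).
#' @param focal_only track only the focal haplotype against the pooled
#'   remainder. Because the non-focal haplotypes are exchangeable,
#'   lumping them leaves the focal-frequency law exactly unchanged
#'   (multinomial aggregation) while making the sweep over initial
#'   frequencies much faster; `final_counts` then has two columns.
#' @return object of class `"drift_sim"`: list with
#'   `final_focal_freqs` (length `replicates`), `final_counts`
#'   (replicates x haplotypes matrix of final transmitting-pool counts),
#'   `model`, `replicates`, `seed`.
#' @export
simulate_model <- function(model, replicates = 1000, seed = NULL,
                           check = FALSE, focal_only = FALSE) {
  stopifnot(inherits(model, "demographic_model"))
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  H <- if (focal_only) 2L else model$n_haplotypes
  G <- model$generations
  Ncens <- census_trajectory(model)
  M <- mt_copies(Ncens, model$mt_copy_rule)
  M0 <- mt_copies(model$Ne0, model$mt_copy_rule)
  # founding haplotype counts in the transmitting pool
  freqs0 <- if (focal_only) c(model$i0, 1 - model$i0) else
    c(model$i0, rep((1 - model$i0) / max(H - 1, 1), max(H - 1, 0)))
  init <- largest_remainder(freqs0, M0)
  if (H > 1 && init[1] == 0)
    stop("i0 too small: focal haplotype rounds to zero copies")
  Fem <- matrix(rep(init, each = replicates), replicates, H)

  neutral_step <- function(Fem, Mnext) {
    rmultinom_rows(Mnext, Fem / rowSums(Fem))
  }

  if (model$scenario != "R") {
    for (g in seq_len(G)) {
      Fem <- neutral_step(Fem, M[g])
      if (check) stopifnot(all(rowSums(Fem) == M[g]))
    }
  } else {
    # neutral drift up to and including the bottleneck kill itself
    # (generation t1+1, the first at the reduced census); anticoagulant
    # mortality is indiscriminate, resistance enters among the survivors
    for (g in seq_len(model$t1 + 1L)) {
      Fem <- neutral_step(Fem, M[g])
      if (check) stopifnot(all(rowSums(Fem) == M[g]))
    }
    st <- introduce_resistance(Fem, model, Ncens[model$t1 + 1L], H)
    FemJ <- st$FemJ
    Males <- st$Males
    w <- model$w
    for (g in (model$t1 + 2L):G) {
      Mg <- M[g]
      males_g <- max(Ncens[g] - Mg, 0L)
      step <- selection_mating_step(FemJ, Males, w, Mg, males_g, H)
      FemJ <- step$FemJ
      Males <- step$Males
      if (check) {
        stopifnot(all(rowSums(FemJ) == Mg))
        stopifnot(all(rowSums(Males) == males_g))
      }
    }
    Fem <- FemJ[, 1:H] + FemJ[, H + 1:H] + FemJ[, 2 * H + 1:H]
  }
  freqs <- Fem[, 1] / rowSums(Fem)
  structure(list(final_focal_freqs = freqs, final_counts = Fem,
                 model = model, replicates = replicates, seed = seed),
            class = "drift_sim")
}

#' Seed the resistance allele at the bottleneck (internal)
#'
#' Converts the neutral female haplotype counts into joint
#' haplotype x genotype counts (columns: H x SS, H x RS, H x RR) and
#' creates the male genotype pool. Resistance copies (frequency `p_R0`
#' of 2N alleles) enter as heterozygotes; a fraction `assoc0` of the
#' copies is placed in focal-haplotype individuals (females first, then
#' males), the remainder at random; copies exceeding the available
#' heterozygote slots become homozygotes.
#' @noRd
introduce_resistance <- function(Fem, model, N, H = model$n_haplotypes) {
  reps <- nrow(Fem)
  Mg <- mt_copies(N, model$mt_copy_rule)
  males <- max(N - Mg, 0L)
  copies <- round(model$p_R0 * 2 * N)
  FemJ <- cbind(Fem, matrix(0L, reps, 2 * H))
  Males <- cbind(SS = rep(males, reps), RS = 0L, RR = 0L)
  if (copies == 0) return(list(FemJ = FemJ, Males = Males))
  focal_copies <- round(model$assoc0 * copies)
  for (r in seq_len(reps)) {
    rem <- copies
    # focal females as heterozygotes
    take <- min(focal_copies, FemJ[r, 1])
    FemJ[r, 1] <- FemJ[r, 1] - take
    FemJ[r, H + 1] <- FemJ[r, H + 1] + take
    rem <- rem - take
    # focal heterozygotes among males count toward the association too
    if (rem > 0 && focal_copies - take > 0 && Males[r, "SS"] > 0) {
      mt <- min(focal_copies - take, Males[r, "SS"])
      Males[r, "SS"] <- Males[r, "SS"] - mt
      Males[r, "RS"] <- Males[r, "RS"] + mt
      rem <- rem - mt
    }
    # promote focal heterozygote females to homozygotes if still short
    while (rem > 0 && FemJ[r, H + 1] > 0) {
      FemJ[r, H + 1] <- FemJ[r, H + 1] - 1L
      FemJ[r, 2 * H + 1] <- FemJ[r, 2 * H + 1] + 1L
      rem <- rem - 1L
    }
    # remaining copies at random: non-focal females then males
    if (rem > 0) {
      nonfocal <- FemJ[r, 2:H]
      tot <- sum(nonfocal) + Males[r, "SS"]
      if (tot > 0) {
        take <- min(rem, sum(nonfocal))
        if (take > 0 && sum(nonfocal) > 0) {
          add <- rmultinom_rows(take, matrix(nonfocal / sum(nonfocal), 1))[1, ]
          add <- pmin(add, nonfocal)
          FemJ[r, 2:H] <- FemJ[r, 2:H] - add
          FemJ[r, H + 2:H] <- FemJ[r, H + 2:H] + add
          rem <- rem - sum(add)
        }
        mt <- min(rem, Males[r, "SS"])
        Males[r, "SS"] <- Males[r, "SS"] - mt
        Males[r, "RS"] <- Males[r, "RS"] + mt
        rem <- rem - mt
      }
    }
  }
  storage.mode(FemJ) <- "integer"
  storage.mode(Males) <- "integer"
  list(FemJ = FemJ, Males = Males)
}

#' One generation of selection, mating and resampling (internal)
#'
#' Viability selection weights the (haplotype x genotype) classes; the
#' maternal pool transmits mtDNA plus one allele (genotype-dependent),
#' the paternal pool one allele; offspring genotypes form by independent
#' assortment; daughters and sons are sampled multinomially at the new
#' census split.
#' @noRd
selection_mating_step <- function(FemJ, Males, w, Mg, males_g, H) {
  reps <- nrow(FemJ)
  wf <- rep(w, each = H)                     # column weights over H x 3
  fsel <- sweep(FemJ, 2, wf, `*`)
  fsel <- fsel / rowSums(fsel)
  # maternal transmitted (haplotype, allele): SS -> S, RS -> half, RR -> R
  PS <- fsel[, 1:H] + 0.5 * fsel[, H + 1:H]            # (h, S)
  PR <- 0.5 * fsel[, H + 1:H] + fsel[, 2 * H + 1:H]    # (h, R)
  if (all(rowSums(Males) > 0)) {
    msel <- sweep(Males, 2, w, `*`)
    msel <- msel / rowSums(msel)
    pmR <- msel[, 2] * 0.5 + msel[, 3]                 # paternal R freq
  } else {
    # degenerate one-pool case (mt_copy_rule = "full"): fathers drawn
    # from the same selected pool as mothers
    pmR <- rowSums(PR)
  }
  daughters <- cbind(PS * (1 - pmR),                   # (h, SS)
                     PS * pmR + PR * (1 - pmR),        # (h, RS)
                     PR * pmR)                         # (h, RR)
  qR <- rowSums(PR)                                    # maternal R freq
  sons <- cbind((1 - qR) * (1 - pmR),
                (1 - qR) * pmR + qR * (1 - pmR),
                qR * pmR)
  list(FemJ = rmultinom_rows(Mg, daughters),
       Males = rmultinom_rows(males_g, sons))
}

#' @export
print.drift_sim <- function(x, ...) {
  cat(sprintf("Forward simulation: scenario %s, %d replicates\n",
              x$model$scenario, x$replicates))
  q <- stats::quantile(x$final_focal_freqs, c(0.05, 0.5, 0.95))
  cat(sprintf("  final focal frequency: mean %.3f, median %.3f [5%%: %.3f, 95%%: %.3f]\n",
              mean(x$final_focal_freqs), q[2], q[1], q[3]))
  cat(sprintf("  P(final >= 0.72) = %.3f\n", prob_exceed(x, 0.72)))
  invisible(x)
}

#' @export
summary.drift_sim <- function(object, thresholds = c(0.5, 0.72, 0.9), ...) {
  f <- object$final_focal_freqs
  list(mean = mean(f), var = stats::var(f),
       quantiles = stats::quantile(f, c(0.05, 0.25, 0.5, 0.75, 0.95)),
       exceedance = vapply(thresholds, function(t) mean(f >= t), numeric(1)),
       surviving_haplotypes = mean(rowSums(object$final_counts > 0)))
}

#' @export
plot.drift_sim <- function(x, threshold = 0.72, ...) {
  graphics::hist(x$final_focal_freqs, breaks = 30,
                 xlab = "final focal-haplotype frequency",
                 main = sprintf("Scenario %s", x$model$scenario), ...)
  graphics::abline(v = threshold, lty = 2)
  invisible(x)
}

#' Probability that the focal haplotype ends at or above a threshold
#'
#' @param result a [simulate_model()] result.
#' @param threshold frequency threshold (default 0.72, the observed
#'   frequency of the most common control-region haplotype in the
#'   German sample).
#' @return fraction of replicates with final focal frequency
#'   `>= threshold`.
#' @export
prob_exceed <- function(result, threshold = 0.72) {
  stopifnot(inherits(result, "drift_sim"))
  f <- result$final_focal_freqs
  if (length(f) == 0) stop("empty simulation result")
  mean(f >= threshold)
}

#' Smallest initial frequency reaching a target exceedance probability
#'
#' Sweeps the initial focal-haplotype frequency `i0` over a grid,
#' estimates `P(final >= target)` at each grid point by forward
#' simulation, enforces monotonicity by isotonic regression (the
#' probability is non-decreasing in `i0`; simulation noise is smoothed
#' out), and reports the smallest `i0` whose smoothed probability
#' reaches `alpha`, linearly interpolated between the bracketing grid
#' points.
#'
#' @param model_base a [demographic_model()]; its `i0` is swept.
#' @param target final-frequency threshold (default 0.72).
#' @param alpha required exceedance probability (default 0.05).
#' @param grid_step grid resolution on `i0` (default 0.01).
#' @param replicates simulation replicates per grid point (default 1000).
#' @param seed optional RNG seed.
#' @param grid optional explicit grid of `i0` values (overrides
#'   `grid_step`).
#' @return object of class `"threshold_sweep"`: list with `threshold`
#'   (interpolated `i0`, or `NA` if no grid point attains `alpha`),
#'   `attained`, `grid`, `prob`, `prob_smooth`, `max_prob`.
#' @export
threshold_initial_frequency <- function(model_base, target = 0.72,
                                        alpha = 0.05, grid_step = 0.01,
                                        replicates = 1000, seed = NULL,
                                        grid = NULL) {
  stopifnot(inherits(model_base, "demographic_model"))
  if (!is.null(seed)) set.seed(seed)
  M0 <- mt_copies(model_base$Ne0, model_base$mt_copy_rule)
  if (is.null(grid)) grid <- seq(grid_step, 1, by = grid_step)
  grid <- grid[grid * M0 >= 1 & grid <= 1]
  prob <- vapply(grid, function(i0) {
    m <- model_base
    m$i0 <- i0
    sim <- simulate_model(m, replicates = replicates, focal_only = TRUE)
    prob_exceed(sim, target)
  }, numeric(1))
  ps <- stats::isoreg(grid, prob)$yf
  hit <- which(ps >= alpha)
  if (length(hit) == 0) {
    out <- list(threshold = NA_real_, attained = FALSE,
                max_prob = max(ps))
  } else {
    k <- hit[1]
    if (k == 1 || ps[k] == ps[k - 1]) {
      thr <- grid[k]
    } else {
      thr <- grid[k - 1] + (alpha - ps[k - 1]) / (ps[k] - ps[k - 1]) *
        (grid[k] - grid[k - 1])
    }
    out <- list(threshold = thr, attained = TRUE, max_prob = max(ps))
  }
  structure(c(out, list(grid = grid, prob = prob, prob_smooth = ps,
                        target = target, alpha = alpha,
                        model = model_base)),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("Threshold sweep: scenario %s, target %.2f at alpha %.2f\n",
              x$model$scenario, x$target, x$alpha))
  if (x$attained) {
    cat(sprintf("  minimal initial frequency: %.3f\n", x$threshold))
  } else {
    cat(sprintf("  not attained (max probability %.3f)\n", x$max_prob))
  }
  invisible(x)
}

#' @export
plot.threshold_sweep <- function(x, ...) {
  graphics::plot(x$grid, x$prob, pch = 16, cex = 0.6,
                 xlab = "initial focal frequency",
                 ylab = sprintf("P(final >= %.2f)", x$target), ...)
  graphics::lines(x$grid, x$prob_smooth, lwd = 2)
  graphics::abline(h = x$alpha, lty = 2, col = "grey40")
  if (x$attained) graphics::abline(v = x$threshold, lty = 3)
  invisible(x)
}
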