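#' Fit one- or two-phase stretched-exponential uptake kinetics
#'
#' Models the deuterium uptake of one envelope population as
#' `DI(t) = sum_p N_p * (1 - exp(-(k_p * t)^beta_p))` with one or two phases.
#' The one-phase model fixes `N = n_exch`; the two-phase model splits
#' `n_exch` into `N_fast + N_slow = n_exch` with the split fitted (or fixed
#' via `n_fast`). Phase count is chosen by corrected-AIC comparison.
#' Initialisation is multistart over rate scales, seeded and deterministic.
#'
#' @param times Exchange times in seconds.
#' @param di Deuterium incorporation at `times` (back-exchange corrected).
#' @param n_exch Number of exchangeable amides (total amplitude).
#' @param n_fast Optional fixed fast-phase site count (skips fitting the
#'   split).
#' @param beta_bounds Stretch-exponent bounds (default `c(0.3, 1)`; the
#'   narrow lower bound avoids degenerate fits on sparse experimental grids).
#' @param seed Seed for the multistart jitter.
#' @return Object of class `biphasic_fit`: `n_phases`, `phases` (data frame
#'   `phase`, `n_sites`, `k`, `beta`), `residual_norm`, `aicc` (per model).
#' @export
fit_biphasic <- function(times, di, n_exch, n_fast = NULL,
                         beta_bounds = c(0.3, 1), seed = 1L) {
  stopifnot(length(times) == length(di), n_exch > 0)
  if (length(times) < 4L) stop("need >= 4 time points for a 1-phase fit")
  set.seed(as.integer(seed))
  n <- length(times)

  model1 <- function(p, t) n_exch * (1 - exp(-(exp(p[1]) * t)^p[2]))
  mid <- times[which.min(abs(di - n_exch / 2))]
  k0 <- log(log(2)) - log(mid)
  fit1 <- NULL
  for (lk in k0 + c(-2, 0, 2)) for (b0 in c(0.6, 1.0)) {
    o <- stats::optim(c(lk, b0), function(p) sum((di - model1(p, times))^2),
                      method = "L-BFGS-B",
                      lower = c(k0 - 12, beta_bounds[1]),
                      upper = c(k0 + 12, beta_bounds[2]))
    if (is.null(fit1) || o$value < fit1$value) fit1 <- o
  }

  fit2 <- NULL
  if (length(times) >= 6L) {
    # parameters: logit split (unless fixed), log k1, beta1, log k2, beta2
    split_free <- is.null(n_fast)
    model2 <- function(p, t) {
      if (split_free) {
        nf <- n_exch * stats::plogis(p[1]); off <- 1L
      } else {
        nf <- n_fast; off <- 0L
      }
      ns <- n_exch - nf
      nf * (1 - exp(-(exp(p[off + 1]) * t)^p[off + 2])) +
        ns * (1 - exp(-(exp(p[off + 3]) * t)^p[off + 4]))
    }
    npar <- if (split_free) 5L else 4L
    lower <- c(if (split_free) -6, k0 - 14, beta_bounds[1], k0 - 14, beta_bounds[1])
    upper <- c(if (split_free) 6, k0 + 14, beta_bounds[2], k0 + 14, beta_bounds[2])
    for (dk in c(1, 2, 4)) for (s0 in c(0, 0.8, -0.8)) {
      start <- c(if (split_free) s0, k0 + dk, 0.9, k0 - dk, 0.9)
      o <- try(stats::optim(start, function(p) sum((di - model2(p, times))^2),
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(maxit = 1000)), silent = TRUE)
      if (inherits(o, "try-error")) next
      if (is.null(fit2) || o$value < fit2$value) fit2 <- o
    }
  }

  # corrected AIC; the correction term is undefined for n <= k + 1, where
  # plain AIC is used instead (sparse experimental grids)
  aicc <- function(rss, k) {
    rss <- max(rss, 1e-12)
    n * log(rss / n) + 2 * k +
      if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else 0
  }
  a1 <- aicc(fit1$value, 2L)
  a2 <- if (is.null(fit2)) Inf else aicc(fit2$value, if (is.null(n_fast)) 5L else 4L)

  if (a2 < a1) {
    p <- fit2$par
    if (is.null(n_fast)) {
      nf <- n_exch * stats::plogis(p[1]); p <- p[-1]
    } else nf <- n_fast
    ph <- data.frame(phase = c("A", "B"),
                     n_sites = c(nf, n_exch - nf),
                     k = exp(p[c(1, 3)]), beta = p[c(2, 4)])
    ph <- ph[order(-ph$k), ]
    ph$phase <- c("fast", "slow")
    res <- structure(list(n_phases = 2L, phases = ph,
                          residual_norm = sqrt(fit2$value),
                          aicc = c(one = a1, two = a2)),
                     class = "biphasic_fit")
  } else {
    ph <- data.frame(phase = "single", n_sites = n_exch,
                     k = exp(fit1$par[1]), beta = fit1$par[2])
    res <- structure(list(n_phases = 1L, phases = ph,
                          residual_norm = sqrt(fit1$value),
                          aicc = c(one = a1, two = a2)),
                     class = "biphasic_fit")
  }
  rownames(res$phases) <- NULL
  res
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat(sprintf("%d-phase stretched-exponential fit (resid %.3g)\n",
              x$n_phases, x$residual_norm))
  print.data.frame(x$phases, digits = 4)
  invisible(x)
}

#' Protection factor from observed and random-coil rates
#'
#' `Pf = k_rc / k_obs`: the factor by which structure slows exchange
#' relative to the unstructured chain; `Pf = 1` means random-coil-like,
#' large Pf means strong protection. A zero observed rate yields `Inf`
#' (classified blue).
#'
#' @param k_obs Observed exchange rate in per second; `>= 0`.
#' @param k_rc_avg Random-coil reference rate in per second; `> 0`.
#' @return Protection factor (unitless, possibly `Inf`).
#' @export
protection_factor <- function(k_obs, k_rc_avg) {
  if (any(k_rc_avg <= 0)) stop("random-coil rate must be > 0")
  if (any(k_obs < 0)) stop("observed rate must be >= 0")
  ifelse(k_obs == 0, Inf, k_rc_avg / k_obs)
}

#' Colour class of a protection factor
#'
#' Half-open classes: red `Pf < 10`, orange `10 <= Pf < 100`, green
#' `100 <= Pf < 1000`, blue `Pf >= 1000`. Prolines are black (no amide);
#' undetermined values (`NA`) are grey.
#'
#' @param pf Protection factor(s); `>= 0` or `Inf`, `NA` for undetermined.
#' @param is_proline Logical (recycled): positions without a backbone amide.
#' @return Character vector of classes.
#' @export
classify_pf <- function(pf, is_proline = FALSE) {
  is_proline <- rep_len(is_proline, length(pf))
  out <- ifelse(is.na(pf), "grey",
         ifelse(pf < 10, "red",
         ifelse(pf < 100, "orange",
         ifelse(pf < 1000, "green", "blue"))))
  out[is_proline] <- "black"
  out
}

#' Largest-remainder rounding of phase site counts
#'
#' Rounds continuous fitted site counts to integers constrained to sum to
#' `n_exch`.
#'
#' @param n_sites Continuous site counts.
#' @param n_exch Target integer sum.
#' @return Integer vector summing to `n_exch`.
#' @export
round_site_counts <- function(n_sites, n_exch) {
  if (length(n_sites) == 0) return(integer(0))
  scaled <- n_sites / sum(n_sites) * n_exch
  base <- floor(scaled)
  rem <- n_exch - sum(base)
  if (rem > 0) {
    extra <- order(scaled - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split analysed peptides into dimer and monomer pools
#'
#' Bimodal peptides whose minor/major abundance ratio is below `cutoff`
#' contribute their major population to the helical-dimer pool (relative
#' abundance taken as one) and their minor population to the hairpin-monomer
#' pool. Unimodal peptides join both pools. Bimodal peptides with ratio at
#' or above `cutoff` are treated as having relative abundance approximately
#' one; both their populations go to the dimer pool and are flagged
#' ambiguous.
#'
#' @param peptides List of analysed-peptide entries, each a list with
#'   elements `peptide` (a [peptide_record()]), `is_bimodal`, `ratio`
#'   (minor/major), and `populations`: a named list (`major`, `minor` for
#'   bimodal; `single` for unimodal) whose entries carry `pf_phases`, a data
#'   frame with columns `pf` and `n_sites` (integer sites per phase).
#' @param cutoff Abundance boundary between "< 1" and "approximately 1"
#'   (default 0.75).
#' @return List with elements `dimer` and `monomer`; each pool is a list of
#'   entries `peptide`, `pf_phases`, `abundance`, `ambiguous`.
#' @export
pool_peptides <- function(peptides, cutoff = 0.75) {
  dimer <- list(); monomer <- list()
  for (entry in peptides) {
    if (!isTRUE(entry$is_bimodal)) {
      e <- list(peptide = entry$peptide,
                pf_phases = entry$populations$single$pf_phases,
                abundance = 1, ambiguous = FALSE)
      dimer[[length(dimer) + 1L]] <- e
      monomer[[length(monomer) + 1L]] <- e
    } else if (entry$ratio < cutoff) {
      dimer[[length(dimer) + 1L]] <- list(
        peptide = entry$peptide,
        pf_phases = entry$populations$major$pf_phases,
        abundance = 1, ambiguous = FALSE)
      monomer[[length(monomer) + 1L]] <- list(
        peptide = entry$peptide,
        pf_phases = entry$populations$minor$pf_phases,
        abundance = entry$ratio, ambiguous = FALSE)
    } else {
      for (popn in c("major", "minor")) {
        dimer[[length(dimer) + 1L]] <- list(
          peptide = entry$peptide,
          pf_phases = entry$populations[[popn]]$pf_phases,
          abundance = 1, ambiguous = TRUE)
      }
    }
  }
  list(dimer = dimer, monomer = monomer)
}

# ---- residue-level assignment ------------------------------------------

# Distinct arrangements of a multiset (values may repeat).
.multiset_permutations <- function(values) {
  values <- sort(values)
  n <- length(values)
  if (n <= 1L) return(list(values))
  out <- list()
  recurse <- function(remaining, acc) {
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (v in unique(remaining)) {
      i <- match(v, remaining)
      recurse(remaining[-i], c(acc, v))
    }
  }
  recurse(values, numeric(0))
  out
}

.n_multiset_perms <- function(values) {
  tab <- table(values)
  exp(lgamma(length(values) + 1) - sum(lgamma(tab + 1)))
}

# Inconsistency cost of an assignment: sum over residues covered by >= 2
# peptides of the variance (population, i.e. mean squared deviation) of the
# comparison value across covering peptides.
.assignment_cost <- function(assign_list, positions_list, L, level) {
  vals <- vector("list", L)
  for (i in seq_along(assign_list)) {
    pos <- positions_list[[i]]
    v <- assign_list[[i]]
    for (j in seq_along(pos)) {
      vals[[pos[j]]] <- c(vals[[pos[j]]], v[j])
    }
  }
  cost <- 0
  for (r in seq_len(L)) {
    v <- vals[[r]]
    if (length(v) >= 2L) {
      x <- if (level == "class") .class_index(v) else log10(v)
      cost <- cost + mean((x - mean(x))^2)
    }
  }
  cost
}

.class_index <- function(pf) {
  ifelse(pf < 10, 0, ifelse(pf < 100, 1, ifelse(pf < 1000, 2, 3)))
}

#' Resolve residue-level protection factors from overlapping peptides
#'
#' Each pool peptide carries a multiset of per-residue protection factors
#' (each phase's Pf repeated by its integer site count). Starting from a
#' seeded random assignment of the multiset onto the peptide's exchangeable
#' positions, the optimiser permutes values within peptides (swap moves that
#' never change a peptide's multiset) to reduce the inconsistency cost: the
#' sum over covered residues of the variance of the assigned values across
#' covering peptides (compared at colour-class level by default, or on
#' log10 Pf with `level = "exact"`). Convergence is declared at zero cost or
#' after `patience` proposals without improvement; the best of `restarts`
#' seeded restarts is kept. Small instances (state space at most
#' `exhaustive_limit` arrangements) are solved by exhaustive enumeration
#' instead. If no zero-cost assignment exists the best assignment is
#' returned with the conflicting residues reported, never silently.
#'
#' @param pool A pool from [pool_peptides()]: list of entries with `peptide`
#'   and `pf_phases` (`pf`, `n_sites`).
#' @param sequence Parent protein amino-acid string.
#' @param seed Integer seed.
#' @param max_iter Maximum proposals per restart (default 20000).
#' @param restarts Number of random restarts (default 20).
#' @param patience Proposals without improvement before stopping (default
#'   200).
#' @param level `"class"` (default) or `"exact"` agreement.
#' @param exhaustive_limit State-space bound for exhaustive search (1e5).
#' @param n_term_excluded Per-peptide N-terminal exclusion (default 2).
#' @return Object of class `pf_map`: data frame with columns `residue`
#'   (index), `res` (letter), `pf` (consensus, geometric mean across
#'   covering peptides; `NA` when uncovered), `n_cover`, `class`, `status`
#'   (`ok`, `conflict`, `undetermined`, `proline`); attributes `cost`,
#'   `converged`, `conflicts`.
#' @export
assign_residue_pf <- function(pool, sequence, seed = 17L, max_iter = 20000L,
                              restarts = 20L, patience = 200L,
                              level = c("class", "exact"),
                              exhaustive_limit = 1e5,
                              n_term_excluded = 2L) {
  level <- match.arg(level)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  res_letters <- strsplit(sequence, "")[[1]]
  if (!length(pool)) stop("empty peptide pool")

  positions_list <- lapply(pool, function(e) {
    e$peptide$start + exchangeable_positions(e$peptide, n_term_excluded) - 1L
  })
  multisets <- lapply(pool, function(e) {
    with(e$pf_phases, rep(pf, n_sites))
  })
  for (i in seq_along(pool)) {
    if (length(multisets[[i]]) != length(positions_list[[i]])) {
      stop(sprintf("peptide %s: %d Pf values for %d exchangeable positions",
                   pool[[i]]$peptide$id, length(multisets[[i]]),
                   length(positions_list[[i]])))
    }
  }

  state_space <- prod(vapply(multisets, .n_multiset_perms, numeric(1)))
  set.seed(as.integer(seed))

  if (is.finite(state_space) && state_space <= exhaustive_limit) {
    perms <- lapply(multisets, .multiset_permutations)
    idx <- rep(1L, length(perms))
    best_cost <- Inf; best_assign <- NULL
    repeat {
      assign_list <- lapply(seq_along(perms), function(i) perms[[i]][[idx[i]]])
      cost <- .assignment_cost(assign_list, positions_list, L, level)
      if (cost < best_cost) { best_cost <- cost; best_assign <- assign_list }
      if (best_cost == 0) break
      j <- 1L
      while (j <= length(idx)) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= length(perms[[j]])) break
        idx[j] <- 1L; j <- j + 1L
      }
      if (j > length(idx)) break
    }
    assign_list <- best_assign; cost <- best_cost
  } else {
    best_cost <- Inf; assign_list <- NULL
    for (r in seq_len(restarts)) {
      cur <- lapply(multisets, function(v) sample(v))
      cur_cost <- .assignment_cost(cur, positions_list, L, level)
      stale <- 0L; it <- 0L
      while (cur_cost > 0 && stale < patience && it < max_iter) {
        it <- it + 1L
        i <- sample.int(length(cur), 1L)
        if (length(cur[[i]]) < 2L) { stale <- stale + 1L; next }
        jj <- sample.int(length(cur[[i]]), 2L)
        if (cur[[i]][jj[1]] == cur[[i]][jj[2]]) { stale <- stale + 1L; next }
        prop <- cur
        prop[[i]][jj] <- prop[[i]][rev(jj)]
        prop_cost <- .assignment_cost(prop, positions_list, L, level)
        if (prop_cost < cur_cost) {
          # swap moves preserve each peptide's multiset by construction
          stopifnot(identical(sort(prop[[i]]), sort(cur[[i]])))
          cur <- prop; cur_cost <- prop_cost; stale <- 0L
        } else stale <- stale + 1L
      }
      if (cur_cost < best_cost) { best_cost <- cur_cost; assign_list <- cur }
      if (best_cost == 0) break
    }
    cost <- best_cost
  }

  # consensus per residue
  vals <- vector("list", L)
  for (i in seq_along(assign_list)) {
    pos <- positions_list[[i]]
    for (j in seq_along(pos)) {
      vals[[pos[j]]] <- c(vals[[pos[j]]], assign_list[[i]][j])
    }
  }
  pf <- rep(NA_real_, L); n_cover <- integer(L)
  status <- rep("undetermined", L)
  conflicts <- integer(0)
  for (r in seq_len(L)) {
    v <- vals[[r]]
    n_cover[r] <- length(v)
    if (!length(v)) next
    pf[r] <- 10^mean(log10(v))
    agree <- if (level == "class") length(unique(.class_index(v))) == 1L else
      max(abs(log10(v) - mean(log10(v)))) < 1e-9
    status[r] <- if (agree) "ok" else "conflict"
    if (!agree) conflicts <- c(conflicts, r)
  }
  status[res_letters == "P"] <- "proline"
  cls <- classify_pf(pf, is_proline = res_letters == "P")
  cls[status == "conflict"] <- "grey"
  out <- data.frame(residue = seq_len(L), res = res_letters, pf = pf,
                    n_cover = n_cover, class = cls, status = status,
                    stringsAsFactors = FALSE)
  if (length(conflicts)) {
    warning(sprintf("no fully consistent assignment: %d conflicting residue(s): %s",
                    length(conflicts),
                    paste(utils::head(conflicts, 10L), collapse = ", ")))
  }
  structure(out, cost = cost, converged = cost == 0, conflicts = conflicts,
            class = c("pf_map", "data.frame"))
}

#' @export
print.pf_map <- function(x, ...) {
  covered <- sum(!is.na(x$pf))
  cat(sprintf("Residue-level Pf map: %d/%d residues covered, cost %.3g (%s)\n",
              covered, nrow(x), attr(x, "cost"),
              if (attr(x, "converged")) "consistent" else "conflicts remain"))
  tab <- table(factor(x$class, levels = c("red", "orange", "green", "blue",
                                          "grey", "black")))
  cat("  classes:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-residue chart rows for the three chains
#'
#' Duplicates the dimer-pool assignment for the two helical-dimer chains and
#' uses the monomer pool for the hairpin chain, yielding one row per chain
#' and residue (the layout of a three-chain protection bar chart).
#'
#' @param dimer_map,monomer_map `pf_map` objects from [assign_residue_pf()].
#' @return Data frame with columns `chain` (`dimer1`, `dimer2`, `monomer`),
#'   `residue`, `res`, `pf`, `class`, `status`.
#' @export
build_pf_chart <- function(dimer_map, monomer_map) {
  stopifnot(inherits(dimer_map, "pf_map"), inherits(monomer_map, "pf_map"))
  one <- function(map, chain) {
    data.frame(chain = chain, residue = map$residue, res = map$res,
               pf = map$pf, class = map$class, status = map$status,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(dimer_map, "dimer1"), one(dimer_map, "dimer2"),
               one(monomer_map, "monomer"))
  class(out) <- c("pf_chart", "data.frame")
  out
}

#' @export
plot.pf_map <- function(x, ...) {
  cols <- c(red = "firebrick2", orange = "orange", green = "forestgreen",
            blue = "royalblue", grey = "grey70", black = "black")
  graphics::barplot(rep(1, nrow(x)), col = cols[x$class], border = NA,
                    space = 0, xlab = "Residue", yaxt = "n", ...)
  graphics::axis(1)
  invisible(x)
}
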