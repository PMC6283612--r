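#' Queued-ribosome cleavage model
#'
#' Parameters of the generative model for endonucleolytic cleavage behind a
#' stalled ribosome. A lead ribosome arrested at the stall protects
#' `lead_footprint` nt of mRNA 5' of the stall; each trailing (collided)
#' ribosome protects a further `trail_footprint` nt. Cleavage happens at
#' ribosome boundaries, so candidate 3' ends sit at stall-relative distances
#' `lead_footprint + (k - 1) * trail_footprint` for the k-th queued boundary.
#'
#' Two regimes are modelled. In `static` mode the queue persists: each
#' cleavage event independently fires boundaries with probability
#' `cleavage_prob` and (by default) only the most-3' fired boundary yields a
#' fragment, giving trail-footprint-spaced products when firing is
#' stochastic. In `iterative` mode each cleavage creates a new mRNA 3' end at
#' which the queue re-forms, so successive cuts on one molecule recede by
#' `lead_footprint + trail_footprint` nt per cycle -- the cleavage-runoff
#' regime seen when ribosome rescue is disabled.
#'
#' @param lead_footprint nt protected 5' of the stall by the lead ribosome
#'   (default 15).
#' @param trail_footprint nt protected by each queued ribosome (default 30).
#' @param n_ribosomes Queue depth (boundaries available in static mode).
#' @param mode `"static"` or `"iterative"`.
#' @param cleavage_prob Per-boundary (static) or per-cycle (iterative) firing
#'   probability.
#' @param n_events Number of cleavage events to draw.
#' @param jitter Uniform positional jitter half-width (nt) applied to each
#'   site, emulating end heterogeneity; default 0 (exact boundaries).
#' @param seed Integer seed.
#' @return A list of class `queue_model`.
#' @export
queue_model <- function(lead_footprint = 15L, trail_footprint = 30L,
                        n_ribosomes = 4L, mode = c("static", "iterative"),
                        cleavage_prob = 1, n_events = 1000L, jitter = 0L,
                        seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(lead_footprint > 0, trail_footprint > 0,
            cleavage_prob >= 0, cleavage_prob <= 1,
            n_ribosomes >= 1, n_events >= 0, jitter >= 0)
  structure(
    list(lead_footprint = as.integer(lead_footprint),
         trail_footprint = as.integer(trail_footprint),
         n_ribosomes = as.integer(n_ribosomes),
         mode = mode,
         cleavage_prob = cleavage_prob,
         n_events = as.integer(n_events),
         jitter = as.integer(jitter),
         seed = as.integer(seed)),
    class = "queue_model"
  )
}

#' Simulate cleavage-site 3'-end coordinates
#'
#' Draws fragment 3'-end positions (1-based reporter coordinates) from a
#' [queue_model] on a stalling reporter. See [queue_model()] for the two
#' regimes. Sites that would fall before position 1 are discarded; the count
#' of discarded events is attached as attribute `n_discarded`.
#'
#' @param model A [queue_model].
#' @param reporter A [reporter_spec] with a stall element.
#' @param keep_all In static mode, keep every fired boundary per event
#'   (diagnostic mode exposing the full boundary ladder) instead of only the
#'   most-3' one.
#' @return Integer vector of 3'-end coordinates, one per retained cleavage,
#'   with attribute `n_discarded`.
#' @export
#' @examples
#' rep <- synthetic_reporter()
#' sites <- simulate_cleavage_sites(queue_model(n_ribosomes = 1, n_events = 5), rep)
#' unique(rep$stall_start - sites)  # 15 nt upstream of the stall
simulate_cleavage_sites <- function(model, reporter, keep_all = FALSE) {
  stopifnot(inherits(model, "queue_model"), inherits(reporter, "reporter_spec"))
  stall <- require_stall(reporter)
  with_seed_local(model$seed, {
    dists <- if (model$mode == "static") {
      boundary <- model$lead_footprint +
        (seq_len(model$n_ribosomes) - 1L) * model$trail_footprint
      if (keep_all) {
        fired <- stats::runif(model$n_events * model$n_ribosomes) <= model$cleavage_prob
        rep(boundary, times = model$n_events)[fired]
      } else {
        vapply(seq_len(model$n_events), function(i) {
          fired <- which(stats::runif(model$n_ribosomes) <= model$cleavage_prob)
          if (length(fired)) boundary[min(fired)] else NA_integer_
        }, integer(1))
      }
    } else {
      # iterative: molecules cleave in cycles, each cut receding by
      # lead + trail from the previous 3' end; a failed cycle ends the
      # molecule and a fresh one starts at the stall.
      step <- model$lead_footprint + model$trail_footprint
      out <- integer(0)
      d <- step
      while (length(out) < model$n_events) {
        if (stats::runif(1) <= model$cleavage_prob) {
          out <- c(out, d)
          d <- d + step
          if (stall - d < 1L) d <- step  # ran off the 5' end: new molecule
        } else {
          d <- step
        }
        if (model$cleavage_prob == 0) break
      }
      out
    }
    dists <- dists[!is.na(dists)]
    if (model$jitter > 0L && length(dists)) {
      dists <- dists + sample.int(2L * model$jitter + 1L, length(dists),
                                  replace = TRUE) - model$jitter - 1L
    }
    sites <- stall - dists
    keep <- sites >= 1L
    structure(as.integer(sites[keep]), n_discarded = sum(!keep))
  })
}

#' Read-synthesis parameters
#'
#' @param read_length Total read length budget (nt), adapter included.
#' @param per_base_error_rate Per-base substitution probability.
#' @param adapter Adapter appended 3' of each fragment.
#' @param frac_no_adapter Fraction of reads whose adapter ligation failed.
#' @param seed Integer seed.
#' @return A list of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 150L, per_base_error_rate = 0,
                            adapter = "CTGTAGGCACCATCAAT",
                            frac_no_adapter = 0, seed = 1L) {
  stopifnot(per_base_error_rate >= 0, per_base_error_rate < 1,
            frac_no_adapter >= 0, frac_no_adapter <= 1,
            read_length >= 1L, grepl("^[ACGT]+$", toupper(adapter)))
  structure(
    list(read_length = as.integer(read_length),
         per_base_error_rate = per_base_error_rate,
         adapter = toupper(adapter),
         frac_no_adapter = frac_no_adapter,
         seed = as.integer(seed)),
    class = "read_sim_params"
  )
}

#' Synthesize 3'-RACE reads from cleavage sites
#'
#' Each read is the reporter subsequence from the amplification primer to its
#' cleavage site (the fragment 3' end), 5'-truncated to the read-length
#' budget, with the adapter appended 3' (except for the no-adapter fraction)
#' and independent per-base substitution errors applied.
#'
#' @param sites Integer vector of 3'-end coordinates (all `>= primer_start`).
#' @param reporter A [reporter_spec].
#' @param params A [read_sim_params].
#' @return Tibble of reads (`id`, `sequence`, `qualities`) with a logical
#'   column `has_adapter` recording ligation status (ground truth, not
#'   observable in real data).
#' @export
synthesize_reads <- function(sites, reporter, params = read_sim_params()) {
  stopifnot(inherits(reporter, "reporter_spec"),
            inherits(params, "read_sim_params"))
  sites <- as.integer(sites)
  if (any(sites < reporter$primer_start)) {
    stop("cleavage site 5' of the amplification primer (position ",
         reporter$primer_start, ") cannot be amplified", call. = FALSE)
  }
  if (any(sites > nchar(reporter$sequence))) {
    stop("cleavage site beyond reporter end", call. = FALSE)
  }
  n <- length(sites)
  if (n == 0L) {
    return(tibble(id = character(), sequence = character(),
                  qualities = character(), has_adapter = logical()))
  }
  with_seed_local(params$seed, {
    has_adapter <- stats::runif(n) >= params$frac_no_adapter
    templates <- substring(reporter$sequence, reporter$primer_start, sites)
    full <- ifelse(has_adapter, paste0(templates, params$adapter), templates)
    len <- nchar(full)
    start <- pmax(1L, len - params$read_length + 1L)
    seqs <- substring(full, start, len)
    if (params$per_base_error_rate > 0) {
      bases <- c("A", "C", "G", "T")
      seqs <- vapply(seqs, function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        hit <- which(stats::runif(length(ch)) < params$per_base_error_rate)
        for (i in hit) {
          ch[i] <- sample(setdiff(bases, ch[i]), 1L)
        }
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    tibble(
      id = sprintf("frag_%06d", seq_len(n)),
      sequence = seqs,
      qualities = strrep("I", nchar(seqs)),
      has_adapter = has_adapter
    )
  })
}

#' Simulate a transcriptional-shutoff decay course
#'
#' Exponential decay `exp(-ln(2) * t / t_half)` observed at the given
#' timepoints, perturbed per replicate and timepoint by multiplicative
#' lognormal noise with coefficient of variation `noise_cv` (unit mean), the
#' natural noise model for strictly positive normalized blot signals.
#'
#' @param t_half True half-life (minutes).
#' @param times Increasing, non-negative timepoints (minutes after shutoff).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @return Tibble `replicate`, `time`, `abundance`.
#' @export
#' @examples
#' simulate_decay_course(4.7, c(0, 2, 4, 8, 16, 32), noise_cv = 0, n_reps = 1)
simulate_decay_course <- function(t_half, times, noise_cv = 0.1, n_reps = 3L,
                                  seed = 1L) {
  if (!is.numeric(t_half) || t_half <= 0) {
    stop("t_half must be positive", call. = FALSE)
  }
  stopifnot(all(times >= 0), !is.unsorted(times, strictly = TRUE),
            noise_cv >= 0, n_reps >= 1L)
  base <- exp(-log(2) * times / t_half)
  with_seed_local(seed, {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      noise <- if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        stats::rlnorm(length(times), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, length(times))
      tibble(replicate = paste0("rep", r), time = times,
             abundance = base * noise)
    })
  })
}

#' Simulate a logistic growth curve
#'
#' OD600 follows a logistic `carrying_od / (1 + exp(-max_rate * (t - t0)))`
#' with inflection at `t0 = midpoint + lag_shift`, plus additive Gaussian
#' read noise (floored at 0). The derivative of the noiseless curve is
#' maximal at the inflection, so `lag_shift` moves the derivative argmax by
#' exactly that amount -- the lag readout recovered downstream.
#'
#' @param max_rate Logistic rate constant (per hour).
#' @param midpoint Inflection time (hours) of the unshifted curve.
#' @param carrying_od Carrying capacity (OD600 units).
#' @param lag_shift Additional lag (hours) added to the inflection time.
#' @param noise_sd Additive Gaussian noise SD (OD units).
#' @param times Increasing sampling times (hours).
#' @param condition Label stored alongside (drug/concentration/replicate).
#' @param seed Integer seed.
#' @return Tibble `condition`, `time`, `od`.
#' @export
simulate_growth_curve <- function(max_rate = 0.8, midpoint = 9, carrying_od = 1.2,
                                  lag_shift = 0, noise_sd = 0,
                                  times = seq(0, 24, by = 1 / 6),
                                  condition = "ref", seed = 1L) {
  stopifnot(carrying_od > 0, !is.unsorted(times, strictly = TRUE),
            noise_sd >= 0)
  od <- carrying_od / (1 + exp(-max_rate * (times - (midpoint + lag_shift))))
  with_seed_local(seed, {
    if (noise_sd > 0) od <- pmax(0, od + stats::rnorm(length(times), sd = noise_sd))
    tibble(condition = condition, time = times, od = od)
  })
}
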