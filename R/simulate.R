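#' Configuration for one synthetic cohort group
#'
#' The generator emulates a labelled cohort of questionnaire respondents
#' with a single latent severity trait: respondent `i` draws
#' `z_i ~ Normal(mu, 1)`, and every scored answer is driven by an
#' item-specific latent `l_ij = sqrt(rho) * z_i + sqrt(1 - rho) * e_ij`
#' (`e_ij` standard normal), so `rho` controls inter-item correlation and
#' `mu` the between-group separation. Ordinal questions use probit
#' thresholds: the answer that codes 1 is taken when `l >= offset`, the
#' middle level when `offset - ordinal_gap <= l < offset` (for pain
#' frequency the two pain-almost-daily levels sit above the offset, split
#' at `offset + ordinal_gap`). Checklist counts (kinds of pain out of 8,
#' symptoms out of 17) are binomial with latent-linked success probability
#' `pnorm(l - offset)`; ticked tokens are then sampled uniformly without
#' replacement. Silhouette regions tick when their region latent clears its
#' offset, with 1 + Binomial extra areas inside an active region; trunk
#' areas (which feed no coded item) tick at a latent-linked background
#' rate. Missingness is MCAR per question.
#'
#' Randomness is consumed as a fixed-width block of uniforms per
#' respondent, so the same `(config, seed)` always reproduces the same
#' cohort byte for byte and appending respondents never perturbs earlier
#' ones.
#'
#' @param label cohort label (`ACR_POS`, `ACR_NEG`, `FM`, `NON_FM`).
#' @param n cohort size.
#' @param mu latent severity mean (latent units; 0 = reference severity).
#' @param rho latent loading in `[0, 1)`; share of item-latent variance
#'   carried by the common trait.
#' @param item_offsets named numeric vector of per-item probit offsets on
#'   the latent scale (names = [item_names()]); higher = harder to endorse.
#' @param miss_rates named per-question MCAR missingness probabilities in
#'   `[0, 0.15]` for `q1, q2, q3, q4, q5, q6, q13`.
#' @param ordinal_gap spacing between adjacent ordinal thresholds (latent
#'   units, default 1).
#' @param region_extra_p success probability for extra ticked areas within
#'   an active region (default 0.3).
#' @param trunk_offset probit offset for trunk-area ticking (default 1.5).
#' @param seed master seed for the cohort.
#' @return a validated list of class `fd_group_config`.
#' @examples
#' cfg <- group_config("FM", n = 10, mu = 1, seed = 42)
#' generate_cohort(cfg)
#' @export
group_config <- function(label, n, mu = 0, rho = 0.5,
                         item_offsets = default_item_offsets(),
                         miss_rates = default_miss_rates(),
                         ordinal_gap = 1, region_extra_p = 0.3,
                         trunk_offset = 1.5, seed = 1) {
  cfg <- structure(list(
    label = label, n = as.integer(n), mu = mu, rho = rho,
    item_offsets = item_offsets, miss_rates = miss_rates,
    ordinal_gap = ordinal_gap, region_extra_p = region_extra_p,
    trunk_offset = trunk_offset, seed = as.integer(seed)
  ), class = "fd_group_config")
  validate_group_config(cfg)
  cfg
}

#' @rdname group_config
#' @export
default_item_offsets <- function() {
  ## mild spread of item difficulty around 0; checklist items harder
  ## (their offset acts on the per-token probability, not the item itself)
  c(B_UPPER = -0.3, B_ARM = -0.1, B_LEG = -0.2, PAIN_FREQ = -0.4,
    PAIN_KINDS3 = 0.2, TIRED_FREQ = 0.1, EFFORT = 0.0, SYMPT7 = 0.4,
    RECOG = 0.3)
}

#' @rdname group_config
#' @export
default_miss_rates <- function() {
  ## roughly 1% per question => about 5% of scores missing, the order of
  ## magnitude seen in completed screening leaflets
  setNames(rep(0.008, 7),
           c("q1", "q2", "q3", "q4", "q5", "q6", "q13"))
}

validate_group_config <- function(cfg) {
  if (!cfg$label %in% cohort_labels()) {
    abort(paste0("unknown cohort label: ", cfg$label),
          class = "fd_config_error")
  }
  if (cfg$n < 1) abort("n must be >= 1", class = "fd_config_error")
  if (cfg$rho < 0 || cfg$rho >= 1) {
    abort("rho must lie in [0, 1)", class = "fd_config_error")
  }
  if (!setequal(names(cfg$item_offsets), item_names())) {
    abort("item_offsets must be named by the nine items",
          class = "fd_config_error")
  }
  mr <- cfg$miss_rates
  if (!setequal(names(mr), c("q1", "q2", "q3", "q4", "q5", "q6", "q13")) ||
      any(mr < 0) || any(mr > 0.15)) {
    abort("miss_rates must cover q1..q6, q13 with values in [0, 0.15]",
          class = "fd_config_error")
  }
  if (cfg$region_extra_p < 0 || cfg$region_extra_p > 1) {
    abort("region_extra_p must be a probability", class = "fd_config_error")
  }
  invisible(cfg)
}

## uniform-draw block width per respondent (fixed so substreams are stable)
DRAWS_PER_RESPONDENT <- 65L

#' Generate a synthetic labelled cohort
#'
#' Pure function of its configuration: see [group_config()] for the
#' generative model.
#'
#' @param cfg an `fd_group_config`.
#' @return a validated cohort tibble (see [response_record()]).
#' @export
generate_cohort <- function(cfg) {
  validate_group_config(cfg)
  n <- cfg$n
  U <- with_preserved_rng(cfg$seed, {
    matrix(runif(n * DRAWS_PER_RESPONDENT), nrow = n,
           ncol = DRAWS_PER_RESPONDENT, byrow = TRUE)
  })

  z <- cfg$mu + qnorm(U[, 1])
  lat <- function(e_col) {
    sqrt(cfg$rho) * z + sqrt(1 - cfg$rho) * qnorm(U[, e_col])
  }
  th <- cfg$item_offsets
  gap <- cfg$ordinal_gap

  l_upper <- lat(2); l_arm <- lat(3); l_leg <- lat(4)
  l_q2 <- lat(5); l_q3 <- lat(6); l_q4 <- lat(7)
  l_q5 <- lat(8); l_q6 <- lat(9); l_q13 <- lat(10)

  q2 <- ordinal_from_latent(l_q2, ordinal_levels("q2_pain_freq"),
                            ## both top levels code 1: boundary at the offset
                            c(th[["PAIN_FREQ"]] + gap, th[["PAIN_FREQ"]]))
  q4 <- ordinal_from_latent(l_q4, ordinal_levels("q4_tired_freq"),
                            c(th[["TIRED_FREQ"]], th[["TIRED_FREQ"]] - gap))
  q5 <- ordinal_from_latent(l_q5, ordinal_levels("q5_effort"),
                            c(th[["EFFORT"]], th[["EFFORT"]] - gap))
  q13 <- ordinal_from_latent(l_q13, ordinal_levels("q13_recognition"),
                             c(th[["RECOG"]], th[["RECOG"]] - gap))

  q3_count <- qbinom(U[, 11], 8, pnorm(l_q3 - th[["PAIN_KINDS3"]]))
  q3 <- pick_tokens(pain_descriptors(), q3_count, U[, 12:19, drop = FALSE])

  q6_count <- qbinom(U[, 20], 17, pnorm(l_q6 - th[["SYMPT7"]]))
  q6 <- pick_tokens(symptom_vocabulary(), q6_count,
                    U[, 21:37, drop = FALSE])

  l_trunk <- lat(41)
  areas <- build_areas(
    active = cbind(UPPER_BODY = l_upper >= th[["B_UPPER"]],
                   UPPER_LIMB = l_arm >= th[["B_ARM"]],
                   LOWER_LIMB = l_leg >= th[["B_LEG"]]),
    extra_u = U[, 38:40, drop = FALSE],
    trunk_count = qbinom(U[, 42], 4, pnorm(l_trunk - cfg$trunk_offset)),
    keys = U[, 43:58, drop = FALSE],
    extra_p = cfg$region_extra_p
  )

  miss <- sweep(U[, 59:65, drop = FALSE], 2,
                cfg$miss_rates[c("q1", "q2", "q3", "q4", "q5", "q6", "q13")],
                "<")

  na_if_miss <- function(x, m) replace(x, m, NA_character_)
  na_multi <- function(cells, m) {
    cells[m] <- list(NA_character_)
    cells
  }

  tibble(
    respondent_id = sprintf("%s_%05d", tolower(cfg$label), seq_len(n)),
    label = cfg$label,
    q1_areas = na_multi(areas, miss[, 1]),
    q2_pain_freq = na_if_miss(q2, miss[, 2]),
    q3_pain_kinds = na_multi(q3, miss[, 3]),
    q4_tired_freq = na_if_miss(q4, miss[, 4]),
    q5_effort = na_if_miss(q5, miss[, 5]),
    q6_symptoms = na_multi(q6, miss[, 6]),
    q7_q12 = NA_character_,
    q13_recognition = na_if_miss(q13, miss[, 7]),
    q14_text = NA_character_
  )
}

## three-level ordinal: levels[1] if l >= cuts[1], levels[2] if
## cuts[2] <= l < cuts[1], else levels[3]
ordinal_from_latent <- function(l, levels, cuts) {
  out <- rep(levels[3], length(l))
  out[l >= cuts[2]] <- levels[2]
  out[l >= cuts[1]] <- levels[1]
  out
}

## choose counts[i] tokens for respondent i by ranking that row's keys
pick_tokens <- function(vocabulary, counts, keys) {
  lapply(seq_along(counts), function(i) {
    m <- counts[i]
    if (m == 0L) return(character(0))
    vocabulary[order(keys[i, ])[seq_len(m)]]
  })
}

build_areas <- function(active, extra_u, trunk_count, keys, extra_p) {
  tax <- body_area_taxonomy()
  region_cols <- list(
    UPPER_BODY = which(tax$region == "UPPER_BODY"),
    UPPER_LIMB = which(tax$region == "UPPER_LIMB"),
    LOWER_LIMB = which(tax$region == "LOWER_LIMB")
  )
  trunk_cols <- which(tax$region == "TRUNK_OTHER")
  ## number ticked inside an active region: 1 + Binomial(3, extra_p)
  extra <- matrix(qbinom(extra_u, 3, extra_p), nrow = nrow(extra_u))
  lapply(seq_len(nrow(active)), function(i) {
    picked <- character(0)
    for (r in seq_along(region_cols)) {
      if (!active[i, r]) next
      cols <- region_cols[[r]]
      m <- 1L + extra[i, r]
      picked <- c(picked, tax$code[cols[order(keys[i, cols])[seq_len(m)]]])
    }
    if (trunk_count[i] > 0L) {
      m <- trunk_count[i]
      picked <- c(picked,
                  tax$code[trunk_cols[order(keys[i, trunk_cols])[seq_len(m)]]])
    }
    picked
  })
}

## run code under a fixed seed without touching the caller's RNG state
with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
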