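#' Simulation configuration
#'
#' Defaults emulate the corpus the method was designed for: a gastroenterology
#' knowledge network of 182 diseases, 1,146 clinical manifestations and 513
#' auxiliary examination results; a corpus of 5,040 records over 76 diseases
#' with on average 3.62 diseases per patient. Gold label-set sizes follow a
#' zero-truncated Poisson whose rate is calibrated so the *truncated* mean
#' equals `diseases_per_patient`. Emission, noise and negation probabilities
#' are emulation choices (the source corpus is private), exposed here so
#' studies can move them.
#'
#' @param n_diseases Number of KN diseases (default 182).
#' @param n_manifestations,n_auxiliary Finding pool sizes (1146 / 513).
#' @param n_active_diseases Diseases that actually occur in patients
#'   (default 76); the rest are distractor candidates.
#' @param common_per_disease,occasional_per_disease,auxiliary_per_disease
#'   Integer ranges `c(min, max)` of edges per disease and category.
#' @param p_occasional_reuse_common Probability that an occasional edge of a
#'   disease reuses a finding that is a *common* manifestation of some other
#'   disease — this mixed-category sharing is what makes weight schemes
#'   matter.
#' @param aux_exclusive If `TRUE`, every auxiliary finding belongs to exactly
#'   one disease.
#' @param exclusive_findings If `TRUE`, all per-disease finding sets are
#'   pairwise disjoint (the fully separable regime used in recovery tests).
#' @param p_common_emit,p_occasional_emit,p_auxiliary_emit Per-edge emission
#'   probabilities when a patient has the disease (0.9 / 0.35 / 0.7).
#' @param diseases_per_patient Mean gold-set size (3.62).
#' @param p_noise_finding Expected distractor mentions per true mention,
#'   drawn from findings of unrelated diseases (0.1).
#' @param p_negated_mention Probability a mention is flagged negated (0.1).
#' @param n_patients Corpus size (5040).
#' @param seed Integer seed; mandatory, the generators are fully
#'   deterministic given it.
#' @param script `"ascii"` (word-token surfaces) or `"cjk"` (Han-character
#'   surfaces exercising character tokenization).
#' @return An object of class `dxr_sim_config`.
#' @export
simulation_config <- function(n_diseases = 182L,
                              n_manifestations = 1146L,
                              n_auxiliary = 513L,
                              n_active_diseases = 76L,
                              common_per_disease = c(2L, 4L),
                              occasional_per_disease = c(3L, 6L),
                              auxiliary_per_disease = c(1L, 3L),
                              p_occasional_reuse_common = 0.25,
                              aux_exclusive = FALSE,
                              exclusive_findings = FALSE,
                              p_common_emit = 0.9,
                              p_occasional_emit = 0.35,
                              p_auxiliary_emit = 0.7,
                              diseases_per_patient = 3.62,
                              p_noise_finding = 0.1,
                              p_negated_mention = 0.1,
                              n_patients = 5040L,
                              seed,
                              script = c("ascii", "cjk")) {
  if (missing(seed)) {
    rlang::abort("simulation_config() requires an explicit seed",
                 class = "dxr_contract_error")
  }
  script <- match.arg(script)
  probs <- c(p_occasional_reuse_common, p_common_emit, p_occasional_emit,
             p_auxiliary_emit, p_negated_mention)
  stopifnot(all(probs >= 0 & probs <= 1), p_noise_finding >= 0,
            n_diseases > 0, n_manifestations > 0, n_auxiliary > 0,
            n_active_diseases > 0, n_active_diseases <= n_diseases,
            n_patients > 0, diseases_per_patient > 1)
  cfg <- list(
    n_diseases = as.integer(n_diseases),
    n_manifestations = as.integer(n_manifestations),
    n_auxiliary = as.integer(n_auxiliary),
    n_active_diseases = as.integer(n_active_diseases),
    common_per_disease = as.integer(common_per_disease),
    occasional_per_disease = as.integer(occasional_per_disease),
    auxiliary_per_disease = as.integer(auxiliary_per_disease),
    p_occasional_reuse_common = p_occasional_reuse_common,
    aux_exclusive = isTRUE(aux_exclusive) || isTRUE(exclusive_findings),
    exclusive_findings = isTRUE(exclusive_findings),
    p_common_emit = p_common_emit,
    p_occasional_emit = p_occasional_emit,
    p_auxiliary_emit = p_auxiliary_emit,
    diseases_per_patient = diseases_per_patient,
    p_noise_finding = p_noise_finding,
    p_negated_mention = p_negated_mention,
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    script = script
  )
  structure(cfg, class = "dxr_sim_config")
}

#' @export
print.dxr_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<dxr_sim_config> KN %d diseases (%d active) / %d manifestations",
                     " / %d auxiliary; %d patients, mean %.2f diseases each; seed %d\n"),
              x$n_diseases, x$n_active_diseases, x$n_manifestations,
              x$n_auxiliary, x$n_patients, x$diseases_per_patient, x$seed))
  invisible(x)
}

# rate lambda such that the zero-truncated Poisson mean lambda/(1-e^-lambda) = m
truncated_poisson_rate <- function(m) {
  stopifnot(m > 1)
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 interval = c(1e-8, m), tol = 1e-12)$root
}

# n draws from a zero-truncated Poisson, capped at `cap`
rtpois <- function(n, lambda, cap = Inf) {
  x <- stats::rpois(n, lambda)
  while (any(x == 0L)) {
    z <- x == 0L
    x[z] <- stats::rpois(sum(z), lambda)
  }
  pmin(x, cap)
}

# Han character alphabets for CJK-mode surfaces, fillers and cues (disjoint,
# so rendered filler can never complete a lexicon surface)
.cjk_surface_alphabet <- strsplit(paste0(
  "痛肿胀热咳血晕麻痒疼酸呕泻秘黄红白紫斑疹硬软冷汗乏力悸闷结石溃疡炎",
  "胃肠肝胆脾肺肾心"), "")[[1]]
.cjk_filler_alphabet <- strsplit("患者今日自述既往体检示般情况可神志清查房间", "")[[1]]
.cjk_cues <- c("无", "未", "否认")
.ascii_cues <- c("no", "denies", "without")

# unique random surfaces: words for ascii, 3-character Han strings for cjk
make_surfaces <- function(n, prefix, script) {
  if (script == "ascii") {
    return(sprintf("%s%04d", prefix, seq_len(n)))
  }
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n - length(out) + 10L), function(i) {
      paste(sample(.cjk_surface_alphabet, 3L, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Generate a knowledge network
#'
#' Each disease receives a sampled set of common and occasional
#' manifestations and auxiliary examination results drawn from shared pools,
#' so findings can support several diseases (comorbidity signal overlap);
#' with probability `p_occasional_reuse_common` an occasional edge reuses
#' another disease's common manifestation, giving the finding different
#' categories (hence scheme-dependent weights) on different edges.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @param scheme Weight scheme applied to the generated edges.
#' @return A validated [knowledge_network()].
#' @export
generate_kn <- function(cfg, scheme = scheme_from_label("<137>")) {
  stopifnot(inherits(cfg, "dxr_sim_config"))
  need_m <- cfg$n_diseases *
    (cfg$common_per_disease[2] + cfg$occasional_per_disease[2])
  if (cfg$exclusive_findings && need_m > cfg$n_manifestations) {
    rlang::abort("requested edges exceed available manifestation findings",
                 class = "dxr_contract_error")
  }
  if (cfg$aux_exclusive &&
      cfg$n_diseases * cfg$auxiliary_per_disease[2] > cfg$n_auxiliary) {
    rlang::abort("requested edges exceed available auxiliary findings",
                 class = "dxr_contract_error")
  }
  if (cfg$common_per_disease[2] + cfg$occasional_per_disease[2] > cfg$n_manifestations ||
      cfg$auxiliary_per_disease[2] > cfg$n_auxiliary) {
    rlang::abort("requested edges exceed available findings",
                 class = "dxr_contract_error")
  }
  withr::with_seed(cfg$seed, {
    disease_ids <- sprintf("d%03d", seq_len(cfg$n_diseases))
    man_ids <- sprintf("m%04d", seq_len(cfg$n_manifestations))
    aux_ids <- sprintf("a%04d", seq_len(cfg$n_auxiliary))
    man_names <- make_surfaces(cfg$n_manifestations, "sx", cfg$script)
    aux_names <- make_surfaces(cfg$n_auxiliary, "ax", cfg$script)

    rng <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
    edges <- vector("list", cfg$n_diseases)
    commons_by_disease <- vector("list", cfg$n_diseases)
    next_man <- 1L; next_aux <- 1L
    for (i in seq_len(cfg$n_diseases)) {
      n_com <- rng(cfg$common_per_disease)
      n_occ <- rng(cfg$occasional_per_disease)
      n_aux <- rng(cfg$auxiliary_per_disease)
      if (cfg$exclusive_findings) {
        com <- man_ids[next_man:(next_man + n_com - 1L)]; next_man <- next_man + n_com
        occ <- man_ids[next_man:(next_man + n_occ - 1L)]; next_man <- next_man + n_occ
      } else {
        com <- sample(man_ids, n_com)
        pool_common <- setdiff(unlist(commons_by_disease[seq_len(i - 1L)]), com)
        occ <- character(n_occ)
        for (j in seq_len(n_occ)) {
          reuse <- length(pool_common) > 0 &&
            stats::runif(1) < cfg$p_occasional_reuse_common
          occ[j] <- if (reuse) {
            pick <- sample(pool_common, 1L)
            pool_common <- setdiff(pool_common, pick)
            pick
          } else {
            sample(setdiff(man_ids, c(com, occ[seq_len(j - 1L)])), 1L)
          }
        }
      }
      if (cfg$aux_exclusive) {
        aux <- aux_ids[next_aux:(next_aux + n_aux - 1L)]; next_aux <- next_aux + n_aux
      } else {
        aux <- sample(aux_ids, n_aux)
      }
      commons_by_disease[[i]] <- com
      edges[[i]] <- tibble::tibble(
        finding_id = c(com, occ, aux),
        disease_id = disease_ids[i],
        category = c(rep("common", n_com), rep("occasional", n_occ),
                     rep("auxiliary", n_aux))
      )
    }
    edges <- dplyr::bind_rows(edges) |>
      dplyr::distinct(.data$finding_id, .data$disease_id, .keep_all = TRUE)
    knowledge_network(
      diseases = tibble::tibble(disease_id = disease_ids,
                                disease_name = paste0("dz", substring(disease_ids, 2))),
      findings = tibble::tibble(finding_id = c(man_ids, aux_ids),
                                finding_name = c(man_names, aux_names)),
      edges = edges,
      scheme = scheme
    )
  })
}

#' Generate a patient corpus
#'
#' Per patient: a gold disease set (zero-truncated Poisson size, drawn from
#' the active diseases), finding mentions emitted per gold-disease edge with
#' the category's emission probability, distractor mentions from findings of
#' unrelated diseases, and a fraction of mentions flagged negated.
#' Deterministic given `cfg$seed` (offset from the KN stream so network and
#' corpus draws do not interleave).
#'
#' @param kn A [knowledge_network()] (typically from [generate_kn()]).
#' @param cfg A [simulation_config()].
#' @return A tibble with one row per record: `record_id`, `gold`
#'   (list of disease ids) and `mentions` (list of tibbles with
#'   `finding_id`, `surface`, `negated`).
#' @export
generate_patients <- function(kn, cfg) {
  stopifnot(inherits(kn, "dxr_kn"), inherits(cfg, "dxr_sim_config"))
  active <- utils::head(sort(kn$diseases$disease_id), cfg$n_active_diseases)
  edges_by_disease <- split(kn$edges, kn$edges$disease_id)
  p_emit <- c(occasional = cfg$p_occasional_emit,
              common = cfg$p_common_emit,
              auxiliary = cfg$p_auxiliary_emit)
  surface_of <- stats::setNames(kn$findings$finding_name, kn$findings$finding_id)
  connected <- unique(kn$edges$finding_id)
  lambda <- truncated_poisson_rate(cfg$diseases_per_patient)

  withr::with_seed(cfg$seed + 1L, {
    sizes <- rtpois(cfg$n_patients, lambda, cap = length(active))
    records <- purrr::map(seq_len(cfg$n_patients), function(i) {
      gold <- sort(sample(active, sizes[i]))
      ed <- dplyr::bind_rows(edges_by_disease[gold])
      emitted <- unique(ed$finding_id[stats::runif(nrow(ed)) < p_emit[ed$category]])
      noise_pool <- setdiff(connected, unique(ed$finding_id))
      n_noise <- if (length(emitted) && cfg$p_noise_finding > 0) {
        min(stats::rbinom(1L, length(emitted), min(cfg$p_noise_finding, 1)),
            length(noise_pool))
      } else 0L
      findings <- c(emitted, if (n_noise > 0) sample(noise_pool, n_noise))
      negated <- stats::runif(length(findings)) < cfg$p_negated_mention
      tibble::tibble(
        record_id = sprintf("P%05d", i),
        gold = list(gold),
        mentions = list(tibble::tibble(
          finding_id = findings,
          surface = unname(surface_of[findings]),
          negated = negated
        ))
      )
    })
    dplyr::bind_rows(records)
  })
}

#' Render a record's mentions as text
#'
#' Embeds each mention's surface in filler tokens, placing a negation cue
#' immediately before negated surfaces; mentions are separated by more filler
#' tokens than the negation window so a cue can never leak onto the next
#' mention. Filler vocabulary and cue characters are disjoint from surface
#' vocabulary, so dictionary extraction followed by negation scoping recovers
#' exactly the record's affirmed finding set when surfaces are
#' lexicon-unique.
#'
#' @param mentions A mention tibble (`finding_id`, `surface`, `negated`).
#' @param script `"ascii"` or `"cjk"`.
#' @param window Negation window the downstream extractor will use.
#' @param lexicon_surfaces Surfaces the filler must avoid colliding with;
#'   colliding filler tokens are regenerated with a warning.
#' @return A single text string.
#' @export
render_text <- function(mentions, script = c("ascii", "cjk"), window = 2L,
                        lexicon_surfaces = character()) {
  script <- match.arg(script)
  cues <- if (script == "ascii") .ascii_cues else .cjk_cues
  filler_vocab <- if (script == "ascii") {
    sprintf("flr%03d", 1:40)
  } else {
    .cjk_filler_alphabet
  }
  clash <- filler_vocab %in% c(lexicon_surfaces, cues)
  if (any(clash)) {
    rlang::warn("filler token(s) collided with lexicon surfaces; regenerated")
    filler_vocab[clash] <- paste0(filler_vocab[clash],
                                  if (script == "ascii") "x" else "")
    filler_vocab <- setdiff(filler_vocab, c(lexicon_surfaces, cues))
  }
  filler <- function() sample(filler_vocab, window + sample(1:3, 1L), replace = TRUE)
  parts <- filler()
  if (nrow(mentions)) {
    for (i in seq_len(nrow(mentions))) {
      if (mentions$negated[i]) parts <- c(parts, sample(cues, 1L))
      parts <- c(parts, mentions$surface[i], filler())
    }
  }
  paste(parts, collapse = if (script == "ascii") " " else "")
}

#' @rdname render_text
#' @param records Corpus tibble from [generate_patients()].
#' @param kn The companion [knowledge_network()].
#' @param cfg The [simulation_config()] (supplies script and seed; text
#'   rendering uses a third seed offset).
#' @return `render_corpus()` returns `records` with a `text` column added.
#' @export
render_corpus <- function(records, kn, cfg, window = 2L) {
  surfaces <- kn$findings$finding_name
  withr::with_seed(cfg$seed + 2L, {
    records$text <- purrr::map_chr(
      records$mentions, render_text,
      script = cfg$script, window = window, lexicon_surfaces = surfaces)
  })
  records
}
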