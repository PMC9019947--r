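#' Specification of a synthetic coded-EMR cohort
#'
#' Describes a two-class cohort (chronic cough vs non-chronic cough) in
#' which the CC class is a mixture of latent subtypes. Each subtype has a
#' disjoint set of signature diagnosis codes drawn at an elevated rate on
#' top of shared background codes; per-patient event counts are Poisson and
#' code choice is multinomial, the simplest model that produces
#' term-frequency matrices with the block structure a clustering method
#' should recover. Cough-instance schedules are constructed so the
#' 120-day / 8-week chronic-cough rule fires for every CC patient (three or
#' more cough dates spanning at least eight weeks inside the study window)
#' and for no control (at most two cough dates).
#'
#' @param n_patients cohort size.
#' @param cc_fraction fraction of CC patients, in (0, 1).
#' @param n_cc_subtypes number of latent CC subtypes (default 3, the number
#'   of high-purity CC clusters the method is expected to resolve).
#' @param vocab_size total number of distinct 3-digit diagnosis codes,
#'   including the cough code `R05`.
#' @param signature_size signature codes per subtype (disjoint across
#'   subtypes).
#' @param elevation probability that a CC patient's event is drawn from the
#'   subtype signature set rather than the background pool (0 = no signal).
#' @param events_mean Poisson mean of per-patient diagnosis event counts
#'   (cough instances are additional).
#' @param subtype_weights mixing weights of the CC subtypes (default equal);
#'   the preset `"paper-shape"` uses the ratio 30:11:1, echoing the very
#'   unequal CC cluster sizes seen in real cohorts.
#' @param balanced draw exactly `round(n * cc_fraction)` CC patients
#'   (default) instead of binomially.
#' @param n_noise_topics number of correlated nuisance "topics": each
#'   patient, independent of class, concentrates part of its background
#'   mass on one topic's code block. 0 disables.
#' @param noise_concentration probability a background draw comes from the
#'   patient's topic block when topics are enabled.
#' @param seed integer seed; identical specs generate byte-identical tables.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients = 1000L, cc_fraction = 0.5,
                           n_cc_subtypes = 3L, vocab_size = 120L,
                           signature_size = 8L, elevation = 0.7,
                           events_mean = 40, subtype_weights = NULL,
                           balanced = TRUE, n_noise_topics = 0L,
                           noise_concentration = 0.5, seed = 1L) {
  if (cc_fraction <= 0 || cc_fraction >= 1) {
    stop("'cc_fraction' must be in (0, 1)", call. = FALSE)
  }
  if (elevation < 0 || elevation > 1) stop("'elevation' must be in [0, 1]", call. = FALSE)
  if (identical(subtype_weights, "paper-shape")) {
    subtype_weights <- c(30, 11, 1)[seq_len(n_cc_subtypes)]
  }
  subtype_weights <- subtype_weights %||% rep(1, n_cc_subtypes)
  if (length(subtype_weights) != n_cc_subtypes || any(subtype_weights <= 0)) {
    stop("'subtype_weights' must be ", n_cc_subtypes, " positive values",
         call. = FALSE)
  }
  n_background <- vocab_size - 1L - n_cc_subtypes * signature_size
  if (n_background < max(2L, n_noise_topics)) {
    stop(sprintf(paste0("vocab_size = %d cannot hold %d subtype signatures of ",
                        "size %d, the cough code, and a background pool"),
                 vocab_size, n_cc_subtypes, signature_size), call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 cc_fraction = cc_fraction,
                 n_cc_subtypes = as.integer(n_cc_subtypes),
                 vocab_size = as.integer(vocab_size),
                 signature_size = as.integer(signature_size),
                 elevation = elevation, events_mean = events_mean,
                 subtype_weights = subtype_weights / sum(subtype_weights),
                 balanced = isTRUE(balanced),
                 n_noise_topics = as.integer(n_noise_topics),
                 noise_concentration = noise_concentration,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

COUGH_CODE <- "R05"

synthetic_code_pool <- function(n) {
  pool <- sprintf("%s%02d", rep(LETTERS, each = 100L), 0:99)
  pool <- setdiff(pool, COUGH_CODE)
  if (n > length(pool)) stop("vocabulary too large", call. = FALSE)
  pool[seq_len(n)]
}

#' Generate a synthetic coded-EMR cohort with known latent structure
#'
#' @param spec a [synthetic_spec()].
#' @return list with
#'   `events` (long event table: `patient_id`, `event_date`, `code`,
#'   `domain`), `labels` (`patient_id`, `class` = `"CC"`/`"non-CC"`,
#'   `subtype` (`NA` for controls), `group` = `"non-CC"` or `"CC-s<k>"`),
#'   `map` (a `category_map` grouping signature sets, background blocks and
#'   the cough code), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  S <- spec$n_cc_subtypes
  pool <- synthetic_code_pool(spec$vocab_size - 1L)
  sig_sets <- split(pool[seq_len(S * spec$signature_size)],
                    rep(seq_len(S), each = spec$signature_size))
  background <- pool[(S * spec$signature_size + 1L):length(pool)]
  topic_block <- if (spec$n_noise_topics > 0L) {
    split(background, cut(seq_along(background), spec$n_noise_topics,
                          labels = FALSE))
  }

  n <- spec$n_patients
  ids <- sprintf("P%05d", seq_len(n))

  withr::with_seed(spec$seed, {
    if (spec$balanced) {
      n_cc <- round(n * spec$cc_fraction)
      is_cc <- seq_len(n) %in% sample.int(n, n_cc)
    } else {
      is_cc <- runif(n) < spec$cc_fraction
    }
    subtype <- ifelse(is_cc,
                      sample.int(S, n, replace = TRUE,
                                 prob = spec$subtype_weights),
                      NA_integer_)
    topic <- if (spec$n_noise_topics > 0L) {
      sample.int(spec$n_noise_topics, n, replace = TRUE)
    }

    origin <- as.Date("2010-01-01")
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      anchor <- origin + sample.int(2000L, 1L)
      n_ev <- max(1L, rpois(1L, spec$events_mean))
      from_sig <- is_cc[i] & (runif(n_ev) < spec$elevation)
      bg_pool <- background
      if (!is.null(topic_block)) {
        use_topic <- runif(n_ev) < spec$noise_concentration
        bg_codes <- ifelse(use_topic,
                           sample(topic_block[[topic[i]]], n_ev, replace = TRUE),
                           sample(background, n_ev, replace = TRUE))
      } else {
        bg_codes <- sample(bg_pool, n_ev, replace = TRUE)
      }
      codes <- bg_codes
      if (any(from_sig)) {
        codes[from_sig] <- sample(sig_sets[[subtype[i]]], sum(from_sig),
                                  replace = TRUE)
      }
      dates <- anchor + sample.int(120L, n_ev, replace = TRUE) - 1L
      if (is_cc[i]) {
        # three guaranteed qualifying instances (span 60 >= 56 inside the
        # 120-day window) plus a random number of extras
        extra <- sample.int(3L, 1L) - 1L
        cough_dates <- anchor + c(0L, 28L, 60L,
                                  if (extra > 0) sample.int(120L, extra) - 1L)
      } else {
        # at most two cough instances: can never satisfy the rule
        n_cough <- sample.int(2L, 1L)
        cough_dates <- anchor + sample.int(120L, n_cough) - 1L
      }
      rows[[i]] <- data.frame(
        patient_id = ids[i],
        event_date = c(dates, cough_dates),
        code = c(codes, rep(COUGH_CODE, length(cough_dates))),
        domain = "diagnosis", stringsAsFactors = FALSE)
    }
  })
  events <- do.call(rbind, rows)

  labels <- data.frame(patient_id = ids,
                       class = ifelse(is_cc, "CC", "non-CC"),
                       subtype = subtype,
                       group = ifelse(is_cc, paste0("CC-s", subtype), "non-CC"),
                       stringsAsFactors = FALSE)

  map_rows <- rbind(
    data.frame(code = COUGH_CODE, domain = "diagnosis", category = "Cough",
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_len(S), function(s) {
      data.frame(code = sig_sets[[s]], domain = "diagnosis",
                 category = sprintf("Signature-%d", s),
                 stringsAsFactors = FALSE)
    })),
    data.frame(code = background, domain = "diagnosis",
               category = paste0("Background-",
                                 cut(seq_along(background),
                                     max(1L, min(4L, length(background))),
                                     labels = FALSE)),
               stringsAsFactors = FALSE))

  list(events = events, labels = labels, map = as_category_map(map_rows),
       spec = spec)
}

#' Write a synthetic cohort to delimited text files
#'
#' Emits `events.csv`, `labels.csv`, `category_map.csv` under `dir`, in the
#' formats [read_event_table()] and [read_category_map()] read back.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$events, file.path(dir, "events.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(cohort$map, file.path(dir, "category_map.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}

#' Generate cohorts of increasing subtype separability
#'
#' One cohort per elevation level with seeds derived from the base spec, so
#' higher elevation means stronger signature-code signal and higher
#' expected clustering purity.
#'
#' @param spec a [synthetic_spec()] providing all shared settings.
#' @param elevations ascending numeric vector of elevation levels in
#'   \[0, 1\].
#' @return named list of cohorts (names = elevation values).
#' @export
generate_separability_series <- function(spec, elevations) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.unsorted(elevations)) stop("'elevations' must be ascending", call. = FALSE)
  out <- lapply(seq_along(elevations), function(i) {
    sp <- spec
    sp$elevation <- elevations[i]
    sp$seed <- spec$seed + 1000L * i
    generate_cohort(sp)
  })
  names(out) <- as.character(elevations)
  out
}
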