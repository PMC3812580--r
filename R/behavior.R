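# Behavioral annotation handling: parse coded-behavior exports (tab-delimited
# tier exports of a video annotation tool) and summarise them per individual
# and per behavior, the way the pilot-session results table is built.

#' The coded behavior vocabulary
#'
#' Behaviors coded towards the device during pilot sessions: approaches to
#' and recessions from the device (within a 2 m distance), exploratory
#' behavior (smelling, licking, looking, touching, grabbing, climbing), tool
#' use, poking, pushing, hitting, dominance display, and the proximity state
#' itself. Poke, push and hit are point events (zero-length intervals);
#' durations are meaningful for proximity.
#'
#' @format Character vector.
#' @export
behavior_vocabulary <- c("approach", "recession", "explore", "tool_use",
                         "poke", "push", "hit", "display", "proximity")

condition_vocabulary <- c("snare", "hihat", "syllable", "none")

#' Parse a coded-behavior annotation export
#'
#' Reads a tab-delimited export with columns `individual`, `behavior`,
#' `start_ms`, `end_ms` and optionally `condition` (the sound mapping active
#' at the time). Unknown behavior labels, unknown conditions and intervals
#' with `end < start` are rejected with the offending line number.
#'
#' @param file Path to the TSV file.
#' @return A tibble of annotation records.
#' @examples
#' f <- system.file("extdata", "pilot_annotations_synthetic.tsv",
#'                  package = "sonimotion")
#' nrow(parse_annotations(f))
#' @export
parse_annotations <- function(file) {
  if (!file.exists(file)) abort(paste0("no such annotation file: ", file))
  recs <- readr::read_tsv(file, col_types = readr::cols(
    individual = readr::col_character(),
    behavior = readr::col_character(),
    start_ms = readr::col_integer(),
    end_ms = readr::col_integer(),
    .default = readr::col_character()
  ), progress = FALSE)
  probs <- readr::problems(recs)
  if (nrow(probs) > 0L) {
    abort(paste0("malformed annotation line ", probs$row[1] + 1L, ": ", probs$expected[1]))
  }
  if (!"condition" %in% names(recs)) recs$condition <- NA_character_
  line <- seq_len(nrow(recs)) + 1L  # account for the header line
  bad <- which(!recs$behavior %in% behavior_vocabulary)
  if (length(bad)) {
    abort(paste0("line ", line[bad[1]], ": unknown behavior '", recs$behavior[bad[1]], "'"))
  }
  bad <- which(is.na(recs$start_ms) | is.na(recs$end_ms) | recs$end_ms < recs$start_ms)
  if (length(bad)) {
    abort(paste0("line ", line[bad[1]], ": invalid interval (end before start)"))
  }
  bad <- which(!is.na(recs$condition) & !recs$condition %in% condition_vocabulary)
  if (length(bad)) {
    abort(paste0("line ", line[bad[1]], ": unknown condition '", recs$condition[bad[1]], "'"))
  }
  recs[c("individual", "behavior", "start_ms", "end_ms", "condition")]
}

#' Summarise coded behavior records
#'
#' Builds the per-individual interaction table: event counts by behavior,
#' seconds spent in proximity of the device (overlapping individuals count
#' independently, so the group total may exceed the session length), a
#' totals row, and — when condition intervals are supplied — the proportion
#' of session time spent under each sound condition.
#'
#' @param records A tibble of annotation records (see [parse_annotations()]).
#' @param conditions Optional tibble `condition`, `start_ms`, `end_ms`
#'   giving the sound-mapping timeline of the session.
#' @param session_ms Session length used for the condition proportions;
#'   defaults to the total span of `conditions`.
#' @return An object of class `behavior_summary`: `$individuals` (tibble:
#'   `individual`, `proximity_s`, one count column per non-proximity
#'   behavior), `$totals` (one-row tibble of column sums),
#'   `$condition_props` (tibble `condition`, `prop`, or `NULL`) and
#'   `$n_individuals` (individuals with at least one interaction record).
#' @export
summarize_behaviors <- function(records, conditions = NULL, session_ms = NULL) {
  count_behaviors <- setdiff(behavior_vocabulary, "proximity")
  if (nrow(records) == 0L) {
    empty <- tibble(individual = character(), proximity_s = numeric())
    for (b in count_behaviors) empty[[b]] <- integer()
    return(structure(list(individuals = empty,
                          totals = summarise(empty, across(-1, ~ sum(.x))),
                          condition_props = NULL, n_individuals = 0L),
                     class = "behavior_summary"))
  }
  prox <- records %>%
    filter(.data$behavior == "proximity") %>%
    group_by(individual = .data$individual) %>%
    summarise(proximity_s = sum(.data$end_ms - .data$start_ms) / 1000, .groups = "drop")
  counts <- records %>%
    filter(.data$behavior != "proximity") %>%
    count(individual = .data$individual, behavior = .data$behavior) %>%
    tidyr::pivot_wider(names_from = "behavior", values_from = "n", values_fill = 0L)
  for (b in count_behaviors) if (!b %in% names(counts)) counts[[b]] <- 0L
  individuals <- dplyr::full_join(prox, counts, by = "individual") %>%
    mutate(proximity_s = dplyr::coalesce(.data$proximity_s, 0)) %>%
    mutate(across(dplyr::all_of(count_behaviors), ~ dplyr::coalesce(.x, 0L))) %>%
    select(dplyr::all_of(c("individual", "proximity_s", count_behaviors))) %>%
    arrange(.data$individual)
  totals <- individuals %>% summarise(across(-"individual", ~ sum(.x)))
  props <- NULL
  if (!is.null(conditions)) {
    dur <- conditions$end_ms - conditions$start_ms
    if (is.null(session_ms)) session_ms <- sum(dur)
    props <- conditions %>%
      group_by(condition = .data$condition) %>%
      summarise(prop = sum(.data$end_ms - .data$start_ms) / session_ms,
                .groups = "drop")
  }
  structure(list(individuals = individuals, totals = totals,
                 condition_props = props,
                 n_individuals = length(unique(individuals$individual))),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("<behavior_summary>", x$n_individuals, "individuals,",
      format(x$totals$proximity_s), "s total proximity\n")
  print(x$individuals, ...)
  invisible(x)
}

#' @exportS3Method broom::tidy
tidy.behavior_summary <- function(x, ...) {
  x$individuals %>%
    tidyr::pivot_longer(-"individual", names_to = "behavior", values_to = "value")
}

# ---- synthetic pilot-session fixture -------------------------------------

pilot_table <- function() {
  tibble(
    individual = sprintf("C%d", 1:12),
    proximity_s = c(211, 140, 122, 211, 32, 68, 517, 288, 458, 6, 243, 20),
    poke = c(12L, 3L, 19L, 32L, 1L, 2L, 1L, 31L, 20L, 1L, 25L, 2L),
    tool_use = c(2L, 0L, 0L, 3L, 0L, 0L, 0L, 5L, 10L, 0L, 1L, 0L),
    push = c(0L, 0L, 4L, 75L, 0L, 0L, 0L, 35L, 10L, 0L, 90L, 3L),
    hit = c(0L, 0L, 3L, 0L, 0L, 0L, 0L, 51L, 0L, 0L, 0L, 0L),
    display = c(0L, 0L, 0L, 0L, 0L, 2L, 0L, 2L, 0L, 0L, 0L, 0L)
  )
}

#' Synthetic pilot-session annotation records
#'
#' A deterministic, fully synthetic record set whose per-individual counts
#' and proximity durations match the pilot-session interaction table (12
#' individuals, 149 pokes, 21 tool uses, 217 pushes, 54 hits, 4 displays,
#' 2316 s of group proximity). Within-individual event times are invented:
#' each individual occupies one proximity interval and their point events
#' are evenly spaced inside it. Shipped also as a TSV fixture under
#' `extdata/pilot_annotations_synthetic.tsv`.
#'
#' @return A tibble of annotation records.
#' @export
pilot_annotations <- function() {
  tab <- pilot_table()
  conds <- pilot_conditions()
  cond_at <- function(t) {
    i <- findInterval(t, conds$start_ms)
    conds$condition[pmax(pmin(i, nrow(conds)), 1L)]
  }
  purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    start <- (i - 1L) * 120000L
    end <- start + as.integer(row$proximity_s * 1000)
    recs <- tibble(
      individual = row$individual,
      behavior = c("approach", "proximity", "explore", "recession"),
      start_ms = c(start, start, start + 1000L, end),
      end_ms = c(start, end, start + 11000L, end)
    )
    for (b in c("poke", "tool_use", "push", "hit", "display")) {
      k <- row[[b]]
      if (k > 0L) {
        at <- start + 2000L + as.integer(round(seq(0, max(end - start - 4000L, 1L),
                                                   length.out = k)))
        recs <- bind_rows(recs, tibble(individual = row$individual, behavior = b,
                                       start_ms = at, end_ms = at))
      }
    }
    recs$condition <- cond_at(recs$start_ms)
    recs
  }) %>% arrange(.data$start_ms, .data$individual, .data$behavior)
}

#' Synthetic pilot-session sound-condition timeline
#'
#' Partition of the 33-minute pilot session into the sound conditions and
#' their observed time shares: snare 69.5%, hi-hat 1.5%, spoken syllables
#' 17.5%, and 11.5% with no sound mapped or no interaction.
#'
#' @return A tibble `condition`, `start_ms`, `end_ms`.
#' @export
pilot_conditions <- function() {
  session <- 33L * 60000L
  dur <- round(session * c(snare = 0.695, hihat = 0.015,
                           syllable = 0.175, none = 0.115))
  ends <- cumsum(dur)
  tibble(condition = names(dur),
         start_ms = as.integer(c(0, head(ends, -1))),
         end_ms = as.integer(ends))
}
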