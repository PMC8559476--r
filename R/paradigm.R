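# Melodic oddball paradigm generator: high-predictability (Alberti-bass)
# and low-predictability (random-walk) 32-note melodies, 250 ms tones from
# a 31-semitone pool (B3-F6), with pitch/timbre/intensity/glide deviants
# placed under the four-note-group and same-feature-adjacency rules.

note_ms <- 250
notes_per_melody <- 32
midi_pool <- c(59L, 89L)  # B3 .. F6, 31 semitones

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate one melody
#'
#' High-predictability (HP) melodies are Alberti-bass figures: a four-note
#' repeated pitch pattern (root, fifth, third, fifth), 4-periodic before
#' transposition. Low-predictability (LP) melodies emulate the statistical
#' profile of the novel melodies used in melodic oddball designs: a seeded
#' random walk over a diatonic scale with low repetitiveness and a broader
#' local pitch range. Every melody is 32 notes of 250 ms (8 s), gapless,
#' and is transposed upward by 0-5 semitones.
#'
#' @param condition `"HP"` or `"LP"`.
#' @param seed integer seed; melodies are pure functions of
#'   (condition, seed).
#' @param melody_id,block identifiers copied into the event rows.
#' @return event table (one row per note) with the note-event schema.
#' @export
generate_melody <- function(condition = c("HP", "LP"), seed = 1,
                            melody_id = 1L, block = 1L) {
  condition <- match.arg(condition)
  with_seed(seed, {
    transpose <- sample(0:5, 1)
    if (condition == "HP") {
      root <- sample(c(60L, 72L), 1)          # two octaves, as in the design
      pattern <- root + c(0L, 7L, 4L, 7L)     # root, fifth, third, fifth
      midi <- rep(pattern, notes_per_melody / 4)
    } else {
      scale_steps <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)  # major scale degrees
      tonic <- sample(59:64, 1)
      degrees <- as.vector(outer(scale_steps, (0:2) * 12L, "+"))
      degrees <- degrees[tonic + degrees <= midi_pool[2] - 5]
      pos <- sample(seq(4, length(degrees) - 4), 1)
      midi <- integer(notes_per_melody)
      for (i in seq_len(notes_per_melody)) {
        midi[i] <- tonic + degrees[pos]
        step <- sample(c(-3:-1, 1:3), 1)
        pos <- pos + step
        if (pos < 1) pos <- 1 + (1 - pos)
        if (pos > length(degrees)) pos <- length(degrees) - (pos - length(degrees))
      }
    }
    midi <- midi + transpose
    stopifnot(all(midi >= midi_pool[1]), all(midi <= midi_pool[2]))
    data.frame(
      onset_ms = (seq_len(notes_per_melody) - 1) * note_ms,
      duration_ms = note_ms,
      midi = as.integer(midi),
      cents_offset = 0,
      feature = "standard",
      note_index = seq_len(notes_per_melody),
      melody_id = melody_id,
      block = block,
      condition = condition,
      stringsAsFactors = FALSE
    )
  })
}

#' Place deviants in a melody
#'
#' Segments the melody into groups of four notes, selects one distinct
#' group per requested feature, and places the deviant uniformly at random
#' within its group. Pitch deviants are realised as a +50 cent offset;
#' other features are labelled only. At most one deviant feature per note.
#'
#' @param melody event table from [generate_melody()].
#' @param features deviant features to place, each once.
#' @param seed integer seed.
#' @return the labelled melody.
#' @export
place_deviants <- function(melody,
                           features = c("pitch", "timbre", "intensity", "glide"),
                           seed = 1) {
  n_groups <- nrow(melody) %/% 4
  if (length(features) > n_groups)
    stopf("cannot place %d deviants in %d four-note groups",
          length(features), n_groups)
  with_seed(seed, {
    groups <- sample(seq_len(n_groups), length(features))
    within <- sample(4, length(features), replace = TRUE)
    idx <- (groups - 1) * 4 + within
    melody$feature[idx] <- features
    melody$cents_offset[idx[features == "pitch"]] <- 50
  })
  melody
}

#' Convert MIDI pitch to frequency
#'
#' Twelve-tone equal temperament with A4 (MIDI 69) at 440 Hz.
#'
#' @param midi MIDI note number(s).
#' @param cents_offset detuning in cents (a +50 cent pitch deviant
#'   multiplies frequency by `2^(50/1200)`).
#' @return frequency in Hz.
#' @export
midi_to_hz <- function(midi, cents_offset = 0) {
  440 * 2^((midi - 69) / 12 + cents_offset / 1200)
}

#' Build a session's event table for one condition
#'
#' Each condition comprises `blocks` consecutive blocks. Every block opens
#' with a deviant-free lead-in melody followed by `melodies_per_block`
#' deviant-bearing melodies (one deviant per feature per melody). Melodies
#' are gapless and consecutive. No deviant ever directly follows another
#' deviant of the same feature, across melody boundaries included.
#'
#' @param condition `"HP"` or `"LP"`.
#' @param blocks number of blocks (default 3).
#' @param melodies_per_block deviant-bearing melodies per block; the
#'   default 48 yields 144 deviants per feature per condition.
#' @param features deviant features.
#' @param seed integer seed.
#' @return event table for the whole condition with attribute
#'   `"deviant_counts"` (per-feature totals).
#' @export
build_session <- function(condition = c("HP", "LP"), blocks = 3,
                          melodies_per_block = 48,
                          features = c("pitch", "timbre", "intensity", "glide"),
                          seed = 1) {
  condition <- match.arg(condition)
  stopifnot(melodies_per_block >= 1)
  out <- list()
  mid <- 0L
  onset0 <- 0
  last_tail <- NULL  # features of the final notes of the previous melody
  for (b in seq_len(blocks)) {
    for (m in 0:melodies_per_block) {
      mid <- mid + 1L
      mseed <- (seed * 100003 + mid * 97) %% 2147483629
      mel <- generate_melody(condition, seed = mseed, melody_id = mid, block = b)
      if (m > 0) {
        reseed <- 0
        repeat {
          cand <- place_deviants(mel, features, seed = mseed + reseed)
          first <- cand$feature[1]
          ok_inner <- !any(cand$feature[-1] != "standard" &
                             cand$feature[-1] == cand$feature[-nrow(cand)])
          ok_edge <- is.null(last_tail) || first == "standard" || first != last_tail
          if (ok_inner && ok_edge) { mel <- cand; break }
          reseed <- reseed + 1
          if (reseed > 1000) stopf("deviant placement constraints unsatisfiable")
        }
      }
      mel$onset_ms <- mel$onset_ms + onset0
      onset0 <- onset0 + nrow(mel) * note_ms
      last_tail <- mel$feature[nrow(mel)]
      out[[mid]] <- mel
    }
  }
  ev <- do.call(rbind, out)
  counts <- table(factor(ev$feature, levels = c("standard", features)))
  attr(ev, "deviant_counts") <- counts
  ev
}

#' Welch two-sample t statistic from summary statistics
#'
#' Welch's t and the Welch-Satterthwaite degrees of freedom from group
#' means, standard deviations and sizes.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (`sd > 0`, `n >= 2`).
#' @return list with elements `t` and `df`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (!all(is.finite(c(mean1, sd1, n1, mean2, sd2, n2))) ||
      sd1 <= 0 || sd2 <= 0 || n1 < 2 || n2 < 2)
    stopf("invalid summary statistics")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  list(
    t = (mean1 - mean2) / sqrt(v1 + v2),
    df = (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  )
}
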