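#' Generate the trial/event plan of the executive reaction-time task
#'
#' Builds the full event timeline of the Go/NoGo executive reaction-time
#' task: blocks of trials sharing a response rule, with each trial carrying
#' an emotion condition (threat-related spider vs. emotionally neutral
#' flower), the relevance of the emotional figure to the task (relevant when
#' the rule attends the figures, irrelevant when it attends the colours),
#' and a go/nogo response type. There are four response rules (attend colour
#' with red = go; attend colour with green = go; attend figure with spider =
#' go; attend figure with flower = go); each rule governs `n_blocks / 4`
#' whole blocks. Within every block the emotion and go/nogo margins are
#' balanced 50/50. In figure-attended (relevant) blocks the go/nogo type is
#' determined by the emotional figure, as the rule dictates; in
#' colour-attended blocks it is assigned independently of emotion.
#'
#' Trial onsets (the triangle presentation) are strictly increasing with an
#' inter-trial interval drawn uniformly from `iti_range`; the response cue
#' follows the triangle onset by 0.3 s. Onsets are snapped to an even sample
#' at 500 Hz so that epochs remain sample-aligned after downsampling to
#' 250 Hz.
#'
#' @param seed Non-negative integer seed; the plan is a deterministic
#'   function of the seed and the size parameters.
#' @param n_blocks Number of blocks (default 16; must be a multiple of 4 so
#'   each rule appears equally often).
#' @param trials_per_block Trials per block (default 64; must be even).
#' @param iti_range Length-2 numeric, inter-trial interval range in seconds
#'   (default 2.5–3.5 s; the pacing is configurable, not prescribed).
#' @param t_start Onset of the first trial in seconds (default 2).
#'
#' @return A tibble with one row per trial and columns `block`, `trial`,
#'   `rule` (1–4), `emotion` ("threat"/"neutral"), `relevance`
#'   ("relevant"/"irrelevant"), `response` ("go"/"nogo"), `onset_s`,
#'   `cue_onset_s`.
#' @export
#' @examples
#' plan <- generate_task_events(seed = 1, n_blocks = 4, trials_per_block = 8)
#' dplyr::count(plan, emotion, relevance)
generate_task_events <- function(seed,
                                 n_blocks = 16L,
                                 trials_per_block = 64L,
                                 iti_range = c(2.5, 3.5),
                                 t_start = 2) {
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0 || seed != round(seed)) {
    abort("`seed` must be a single non-negative integer.")
  }
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  if (n_blocks %% 4L != 0L) abort("`n_blocks` must be a multiple of 4.")
  if (trials_per_block %% 2L != 0L) abort("`trials_per_block` must be even.")
  if (length(iti_range) != 2L || iti_range[1] > iti_range[2] || iti_range[1] <= 0) {
    abort("`iti_range` must be an increasing positive pair of seconds.")
  }

  local_seed(as.integer(seed))

  # each of the 4 rules governs n_blocks/4 whole blocks, in shuffled order
  rule_of_block <- sample(rep(1:4, each = n_blocks %/% 4L))
  half <- trials_per_block %/% 2L

  blocks <- purrr::map(seq_len(n_blocks), function(b) {
    rule <- rule_of_block[b]
    attend_figure <- rule >= 3L
    emotion <- sample(rep(c("threat", "neutral"), each = half))
    if (attend_figure) {
      # figure cues the response: rule 3 spider(threat)=go, rule 4 flower=go
      go_on_threat <- rule == 3L
      response <- ifelse((emotion == "threat") == go_on_threat, "go", "nogo")
    } else {
      response <- sample(rep(c("go", "nogo"), each = half))
    }
    tibble(
      block = b,
      trial = seq_len(trials_per_block),
      rule = rule,
      emotion = emotion,
      relevance = if (attend_figure) "relevant" else "irrelevant",
      response = response
    )
  })
  plan <- dplyr::bind_rows(blocks)

  iti <- runif(nrow(plan), iti_range[1], iti_range[2])
  onset <- t_start + cumsum(c(0, iti[-length(iti)]))
  # snap to the 250 Hz grid (even samples at 500 Hz)
  plan$onset_s <- round(onset * 250) / 250
  plan$cue_onset_s <- plan$onset_s + 0.3
  plan
}

# Deterministic scoped RNG: restore the caller's RNG state on exit.
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  withr::defer(
    {
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    },
    envir = env
  )
  set.seed(seed)
}
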