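#' Gravity-protocol presets
#'
#' Returns the configuration and phase schedule of the standard protocols:
#'
#' * `"drop"` — drop-tower free fall: Baseline 600 s, Microgravity 4.7 s,
#'   Impact 5 s, Baseline 600 s; 150 ms safety margins.
#' * `"centrifuge_6g"` / `"centrifuge_4g"` — centrifugation: Baseline
#'   600 s, 30 s ramp up, 300 s at the target g-level, 30 s ramp down,
#'   300 s post baseline; 2 s safety margins; hypergravity and post phases
#'   analyzed as first/last-minute sub-windows.
#'
#' Phase-dependent modulation factors encode the direction of the reported
#' effects: microgravity raises low/mid units by 4/3 (3 -> 4 Hz) while high
#' units split ~50/50 in sign; the capsule impact drives firing toward a
#' bimodal 8 / 20 Hz profile; hypergravity onset suppresses low/mid units
#' toward 2 Hz; centrifuge ramps push rates toward 8-13 Hz.
#'
#' @param name one of `"drop"`, `"centrifuge_6g"`, `"centrifuge_4g"`.
#' @param scale time-compression factor in `(0, 1]`. Phases of 10 s or more
#'   are scaled down (never below 10 s); shorter phases — the 4.7 s
#'   microgravity window is the scientific object — are kept at full
#'   length. Sub-window splits shrink accordingly.
#' @param ... overrides passed to [synth_config()].
#' @return list with elements `config` ([synth_config()]), `schedule`
#'   ([phase_schedule()]) and `modulation` (tibble `segment`, `subgroup`,
#'   `factor`, `target_hz`).
#' @export
make_preset <- function(name = c("drop", "centrifuge_6g", "centrifuge_4g"),
                        scale = 1, ...) {
  if (!is.character(name) || !name[1] %in% c("drop", "centrifuge_6g", "centrifuge_4g")) {
    rlang::abort(
      sprintf("unknown preset %s; valid presets: drop, centrifuge_6g, centrifuge_4g",
              deparse(name[1])),
      class = "gravimea_invalid_parameter"
    )
  }
  name <- match.arg(name)
  check_that("`scale` must be in (0, 1]" = scale > 0 && scale <= 1)
  sc <- function(d) if (d < 10) d else max(d * scale, 10)

  if (name == "drop") {
    durs <- c(baseline = sc(600), microgravity = 4.7, impact = 5, post = sc(600))
    ends <- cumsum(durs)
    phases <- tibble::tibble(
      label = names(durs),
      start = unname(c(0, ends[-4])),
      end = unname(ends),
      g_level = c(1, 1e-6, 35, 1)
    )
    schedule <- phase_schedule(phases, safety_margin = 0.15,
                               platform = "drop_tower")
    modulation <- tibble::tribble(
      ~segment,       ~subgroup,   ~factor, ~target_hz,
      "microgravity", "low",       4 / 3,   NA,
      "microgravity", "mid",       4 / 3,   NA,
      "microgravity", "high_up",   4 / 3,   NA,
      "microgravity", "high_down", 3 / 4,   NA,
      "impact",       "low",       NA,      8,
      "impact",       "mid",       NA,      8,
      "impact",       "high_up",   NA,      20,
      "impact",       "high_down", NA,      20
    )
  } else {
    g <- if (name == "centrifuge_6g") 6 else 4
    durs <- c(baseline = sc(600), ramp_up = sc(30), hyperg = sc(300),
              ramp_down = sc(30), post = sc(300))
    ends <- cumsum(durs)
    split_len <- min(60, durs[["hyperg"]] / 2, durs[["post"]] / 2)
    phases <- tibble::tibble(
      label = names(durs),
      start = unname(c(0, ends[-5])),
      end = unname(ends),
      g_level = c(1, g / 2, g, g / 2, 1)
    )
    schedule <- phase_schedule(phases, safety_margin = 2,
                               platform = "centrifuge",
                               split_first_last = c("hyperg", "post"),
                               split_len = split_len)
    modulation <- tibble::tribble(
      ~segment,       ~subgroup,   ~factor, ~target_hz,
      "ramp_up",      "low",       NA,      8,
      "ramp_up",      "mid",       NA,      10,
      "ramp_up",      "high_up",   NA,      13,
      "ramp_up",      "high_down", NA,      13,
      "hyperg_onset", "low",       NA,      2,
      "hyperg_onset", "mid",       NA,      2,
      "ramp_down",    "low",       NA,      8,
      "ramp_down",    "mid",       NA,      9,
      "ramp_down",    "high_up",   NA,      11,
      "ramp_down",    "high_down", NA,      11
    )
  }
  list(config = synth_config(...), schedule = schedule, modulation = modulation)
}

# Generation segments: the piecewise-constant rate regime of a schedule.
# Phases whose onset response differs from their steady state (centrifuge
# hypergravity) are split at the first sub-window boundary.
generation_segments <- function(schedule) {
  split_phases <- attr(schedule, "split_first_last") %||% character(0)
  split_len <- attr(schedule, "split_len") %||% 60
  rows <- purrr::pmap(
    list(schedule$label, schedule$start, schedule$end),
    function(label, start, end) {
      if (label == "hyperg" && label %in% split_phases) {
        sl <- min(split_len, (end - start) / 2)
        tibble::tibble(segment = c("hyperg_onset", "hyperg_late"),
                       start = c(start, start + sl), end = c(start + sl, end))
      } else {
        tibble::tibble(segment = label, start = start, end = end)
      }
    }
  )
  dplyr::bind_rows(rows)
}
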