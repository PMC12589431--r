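#' @include simulate.R
NULL

#' Preset benchmark configurations
#'
#' Three shipped benchmark archetypes, one per target family, emulating
#' the common epidemiological / tabular settings in which a single
#' categorical feature must be imputed:
#'
#' * `"binary"`: a heart-disease-style screening table; the target is a
#'   binary indicator (high blood pressure) among mixed binary, ordinal
#'   and nominal companion items.
#' * `"ordinal"`: a diamonds-style grading table; the target is a
#'   5-level ordered grade (color, levels J-F) among ordinal quality
#'   bands.
#' * `"nominal"`: a housing-style listing table; the target is a 5-way
#'   unordered label (city) among property descriptors.
#'
#' In every preset the MAR conditional item carries a high slope so it
#' correlates strongly with the latent trait -- and hence with the target
#' -- mirroring designs where a conditioning variable (carat size, number
#' of rooms, age) relates to the variable being removed.
#'
#' @param name Preset name.
#' @param n Number of cases (default 2000).
#' @param seed Master seed (defaults to a fixed per-preset value).
#' @return A [SimulationConfig-class] for [makeBenchmark()].
#' @examples
#' cfg <- benchmarkPreset("binary", n = 500)
#' bm <- makeBenchmark(cfg)
#' names(bm$variants)
#' @export
benchmarkPreset <- function(name = c("binary", "ordinal", "nominal"),
                            n = 2000L, seed = NULL) {
  name <- match.arg(name)
  if (name == "binary") {
    bank <- itemBank(list(
      twoPLItem(1.6, 0.2, name = "high_bp"),
      grmItem(2.2, c(-1.1, 0.0, 1.1), name = "age_band"),
      twoPLItem(1.8, -0.4, name = "chest_pain"),
      twoPLItem(1.4, 0.6, name = "exercise_angina"),
      twoPLItem(0.8, 1.2, name = "high_fbs"),
      grmItem(1.0, c(-1.2, -0.1, 1.0), name = "chol_band"),
      nrmItem(c(0, 0.9, 1.5), c(0, 0.3, -0.4), name = "rest_ecg"),
      twoPLItem(1.2, -0.8, name = "st_depression"),
      twoPLItem(1.0, 0.0, name = "palpitations"),
      twoPLItem(1.5, 0.9, name = "family_history")),
      levels = list(high_bp = c("no", "yes")))
    cfg <- simulationConfig(n, bank, target = "high_bp",
                            conditional = "age_band",
                            seed = if (is.null(seed)) 101L else seed)
  } else if (name == "ordinal") {
    bank <- itemBank(list(
      grmItem(1.4, c(-1.6, -0.5, 0.5, 1.6), name = "color"),
      grmItem(2.6, c(-1.0, 0.0, 1.0), name = "carat_band"),
      grmItem(1.8, c(-1.8, -0.6, 0.6, 1.8), name = "clarity"),
      grmItem(1.2, c(-1.4, -0.4, 0.6, 1.5), name = "cut"),
      grmItem(0.9, c(-1.0, 0.1, 1.2), name = "depth_band"),
      grmItem(0.7, c(-1.3, 0.0, 1.3), name = "table_band"),
      twoPLItem(1.5, 0.0, name = "premium"),
      grmItem(2.0, c(-0.9, 0.2, 1.1), name = "price_band")),
      levels = list(color = c("J", "I", "H", "G", "F")))
    cfg <- simulationConfig(n, bank, target = "color",
                            conditional = "carat_band",
                            seed = if (is.null(seed)) 202L else seed)
  } else {
    bank <- itemBank(list(
      nrmItem(c(0, 1.2, 2.4, -1.2, 0.6), c(0, 0.4, -0.3, 0.2, -0.2),
              name = "city"),
      grmItem(2.4, c(-1.0, 0.0, 1.0), name = "rooms_band"),
      nrmItem(c(0, 1.0, 2.0), c(0, 0.2, -0.2), name = "furnishing"),
      grmItem(1.8, c(-1.2, -0.1, 1.0), name = "area_band"),
      grmItem(1.5, c(-0.8, 0.6), name = "bathrooms"),
      twoPLItem(1.3, -0.3, name = "main_road"),
      twoPLItem(0.9, 0.4, name = "basement"),
      twoPLItem(1.1, 0.8, name = "guestroom")),
      levels = list(city = c("north", "south", "east", "west", "central")))
    cfg <- simulationConfig(n, bank, target = "city",
                            conditional = "rooms_band",
                            seed = if (is.null(seed)) 303L else seed)
  }
  cfg
}
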