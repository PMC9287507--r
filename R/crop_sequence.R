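# Crop-sequence quality scoring.
#
# The score blends three agronomic components over a multi-year sequence:
# how favourable each crop-to-crop transition is (succession matrix S), how
# well minimum recommended return times are respected, and crop diversity.
# The component weights and tables live in the crop configuration so they can
# be replaced wholesale from a pipeline config file.

#' Default crop configuration
#'
#' Crop vocabulary, succession matrix `S(prev, next)` in `[0, 1]`, minimum
#' recommended return times `R` in years, component weights and the perennial
#' (ley) flag.  Ley-to-ley succession scores 1 and ley has a zero return time:
#' continuous grass/legume ley is agronomically unproblematic, so ley-rich,
#' diverse sequences score high.
#'
#' @param years Sequence length in years (default 7).
#' @return A list with elements `crops`, `S`, `R`, `weights`, `perennial`,
#'   `years`.
#' @export
default_crop_config <- function(years = 7) {
  crops <- c("ley", "spring_cereal", "winter_cereal", "oilseed", "legume",
             "root_crop", "other_crop")
  S <- matrix(c(
    # next:  ley  s_cer w_cer oils  legu  root  other      prev:
           1.0, 0.9,  0.9,  0.8,  0.6,  0.8,  0.7,   # ley
           0.8, 0.2,  0.3,  0.8,  0.8,  0.7,  0.6,   # spring_cereal
           0.8, 0.3,  0.2,  0.8,  0.8,  0.7,  0.6,   # winter_cereal
           0.7, 0.9,  1.0,  0.1,  0.5,  0.6,  0.6,   # oilseed
           0.7, 1.0,  1.0,  0.5,  0.1,  0.7,  0.6,   # legume
           0.7, 0.9,  0.8,  0.5,  0.6,  0.1,  0.6,   # root_crop
           0.7, 0.7,  0.7,  0.6,  0.6,  0.6,  0.4),  # other_crop
    nrow = 7, byrow = TRUE, dimnames = list(crops, crops))
  R <- c(ley = 0, spring_cereal = 2, winter_cereal = 2, oilseed = 5,
         legume = 6, root_crop = 4, other_crop = 2)
  list(crops = crops, S = S, R = R,
       weights = c(pair = 0.5, return = 0.3, diversity = 0.2),
       perennial = "ley", years = years)
}

check_crop_config <- function(cfg) {
  stopifnot(all(cfg$S >= 0 & cfg$S <= 1), all(cfg$R >= 0),
            all(cfg$weights >= 0),
            abs(sum(cfg$weights) - 1) < 1e-9)
  invisible(cfg)
}

#' Score one parcel's crop sequence
#'
#' `score = w_pair * mean succession score of consecutive pairs +
#'  w_return * fraction of years (2..n) whose crop respects its minimum
#'  return time (crops not previously grown in the sequence comply) +
#'  w_div * (distinct crops - 1) / (n - 1)`.
#'
#' @param seq Character vector of crop codes, length `cfg$years`; `NA` slots
#'   mark missing years.
#' @param cfg A crop configuration, see [default_crop_config()].
#' @return Score in `[0, 1]`, or `NA` if any slot is missing (incomplete
#'   sequence).
#' @export
crpseq_parcel <- function(seq, cfg = default_crop_config()) {
  if (length(seq) != cfg$years)
    stop("config error: sequence must have ", cfg$years, " slots")
  if (anyNA(seq)) return(NA_real_)
  bad <- setdiff(seq, cfg$crops)
  if (length(bad) > 0L)
    stop("config error: crop code(s) outside vocabulary: ",
         paste(bad, collapse = ", "))
  n <- cfg$years
  pair <- mean(cfg$S[cbind(seq[-n], seq[-1])])
  ok <- logical(n - 1L)
  for (t in 2:n) {
    prev <- which(seq[seq_len(t - 1L)] == seq[t])
    ok[t - 1L] <- length(prev) == 0L || (t - max(prev)) >= cfg$R[[seq[t]]]
  }
  ret <- mean(ok)
  div <- (length(unique(seq)) - 1) / (n - 1)
  w <- cfg$weights
  unname(w["pair"] * pair + w["return"] * ret + w["diversity"] * div)
}

#' Area-weighted farm-level crop-sequence score
#'
#' Averages parcel scores weighted by parcel area over parcels with complete
#' sequences.  If complete parcels cover less than `coverage` of the farm's
#' cropland area the farm-level score is undefined (`NA`): too little of the
#' rotation is observed to characterise it.
#'
#' @param scores Parcel scores ([crpseq_parcel()]; `NA` = incomplete).
#' @param areas Parcel areas (ha), positive.
#' @param coverage Minimum complete-sequence share of cropland area (0.5).
#' @return Farm score in `[0, 1]` or `NA`.
#' @export
crpseq_farm <- function(scores, areas, coverage = 0.5) {
  stopifnot(length(scores) == length(areas), all(areas > 0))
  complete <- !is.na(scores)
  if (sum(areas[complete]) < coverage * sum(areas)) return(NA_real_)
  sum(scores[complete] * areas[complete]) / sum(areas[complete])
}
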