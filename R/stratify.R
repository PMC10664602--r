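# stratify: activity classes, project stages, and alpha/beta/gamma regions.

#' Activity class thresholds
#'
#' Three strictly increasing pXC50 cutpoints splitting potency into low,
#' middle, high and ultra-high.  Half-open binning is used so every value has
#' exactly one class: low = (-Inf, t1), middle = [t1, t2), high = [t2, t3),
#' ultra_high = [t3, Inf).  Defaults (6, 7, 8) suit most targets; potent
#' series may shift to (7, 8, 9).
#'
#' @param low_mid,mid_high,high_ultra pXC50 cutpoints.
#' @export
activity_thresholds <- function(low_mid = 6, mid_high = 7, high_ultra = 8) {
  t <- c(low_mid = low_mid, mid_high = mid_high, high_ultra = high_ultra)
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    stop("thresholds must be finite and strictly increasing", call. = FALSE)
  }
  structure(as.list(t), class = "activity_thresholds")
}

.activity_levels <- c("low", "middle", "high", "ultra_high")
.stage_levels <- c("early", "middle", "late")
.region_levels <- c("alpha", "beta", "gamma", "none")

#' Assign activity classes from pXC50
#'
#' @param pxc50 numeric vector of finite potencies.
#' @param thresholds an [activity_thresholds()] object.
#' @return factor with levels low/middle/high/ultra_high.
#' @export
assign_activity_class <- function(pxc50, thresholds = activity_thresholds()) {
  stopifnot(inherits(thresholds, "activity_thresholds"))
  if (any(!is.finite(pxc50))) stop("non-finite pXC50", call. = FALSE)
  cuts <- c(-Inf, thresholds$low_mid, thresholds$mid_high,
            thresholds$high_ultra, Inf)
  cut(pxc50, breaks = cuts, labels = .activity_levels, right = FALSE)
}

#' Assign early/middle/late project stages
#'
#' In `pseudo_time` mode records are sorted by ascending pseudo-time
#' distance and split by cumulative fractions: the first `floor(f1*n)`
#' records are early, up to `floor((f1+f2)*n)` middle, the remainder late.
#' In `dated` mode records are sorted by date (ties by `source_row`) and
#' split after the given cumulative compound-count cutpoints.
#'
#' @param records record `data.frame`.
#' @param pseudo_time a [pseudo_time_order()] map (pseudo_time mode).
#' @param fractions stage fractions summing to 1 (default `c(0.5, 0.25, 0.25)`).
#' @param cutpoints increasing cumulative compound counts ending stages 1 and
#'   2 (dated mode), e.g. `c(500, 1000)`.
#' @param mode `"pseudo_time"` or `"dated"`.
#' @return factor of stages aligned with `records`.
#' @export
assign_stages <- function(records, pseudo_time = NULL,
                          fractions = c(0.5, 0.25, 0.25),
                          cutpoints = NULL,
                          mode = c("pseudo_time", "dated")) {
  mode <- match.arg(mode)
  n <- nrow(records)
  if (mode == "pseudo_time") {
    if (is.null(pseudo_time) || !inherits(pseudo_time, "pseudo_time_map")) {
      stop("pseudo_time mode needs a pseudo_time_map", call. = FALSE)
    }
    stopifnot(length(pseudo_time$distances) == n)
    if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3) {
      stop("fractions must be 3 values summing to 1", call. = FALSE)
    }
    b1 <- floor(fractions[1] * n)
    b2 <- floor((fractions[1] + fractions[2]) * n)
    ord <- pseudo_time$order
  } else {
    if (any(is.na(records$date))) stop("dated mode: missing dates", call. = FALSE)
    if (is.null(cutpoints) || length(cutpoints) != 2 || any(diff(cutpoints) <= 0)) {
      stop("dated mode needs 2 strictly increasing cutpoints", call. = FALSE)
    }
    if (cutpoints[2] > n || cutpoints[1] < 1) {
      stop("cutpoint outside data range: ",
           paste(cutpoints[cutpoints > n | cutpoints < 1], collapse = ", "),
           call. = FALSE)
    }
    b1 <- cutpoints[1]
    b2 <- cutpoints[2]
    ord <- order(records$date, records$source_row)
  }
  stage <- character(n)
  stage[ord[seq_len(b1)]] <- "early"
  if (b2 > b1) stage[ord[seq(b1 + 1, b2)]] <- "middle"
  if (n > b2) stage[ord[seq(b2 + 1, n)]] <- "late"
  factor(stage, levels = .stage_levels)
}

#' Assign alpha/beta/gamma regions
#'
#' alpha: early-stage compounds with at least middle activity (the focus
#' candidates).  beta: middle/late-stage compounds with low or middle
#' activity.  gamma: middle/late-stage compounds with high or ultra-high
#' activity (the rediscovery reference).  Early low-activity compounds fall
#' in no region (`none`).
#'
#' @param stage,activity_class aligned factors from [assign_stages()] and
#'   [assign_activity_class()].
#' @return factor with levels alpha/beta/gamma/none.
#' @export
assign_regions <- function(stage, activity_class) {
  stopifnot(length(stage) == length(activity_class))
  early <- stage == "early"
  activeish <- activity_class %in% c("middle", "high", "ultra_high")
  high <- activity_class %in% c("high", "ultra_high")
  region <- rep("none", length(stage))
  region[early & activeish] <- "alpha"
  region[!early & !high] <- "beta"
  region[!early & high] <- "gamma"
  factor(region, levels = .region_levels)
}

#' Label a project dataset with stage, activity class and region
#'
#' Convenience wrapper running [assign_activity_class()], [assign_stages()]
#' and [assign_regions()] and returning the records with `stage`,
#' `activity_class` and `region` columns appended (plus `distance` and
#' `pseudo_rank` in pseudo-time mode).
#'
#' @inheritParams assign_stages
#' @param thresholds an [activity_thresholds()] object.
#' @export
label_dataset <- function(records, thresholds = activity_thresholds(),
                          pseudo_time = NULL,
                          fractions = c(0.5, 0.25, 0.25),
                          cutpoints = NULL,
                          mode = c("pseudo_time", "dated")) {
  mode <- match.arg(mode)
  if (mode == "pseudo_time" && is.null(pseudo_time)) {
    pseudo_time <- pseudo_time_order(records)
  }
  records$activity_class <- assign_activity_class(records$pxc50, thresholds)
  records$stage <- assign_stages(records, pseudo_time = pseudo_time,
                                 fractions = fractions,
                                 cutpoints = cutpoints, mode = mode)
  records$region <- assign_regions(records$stage, records$activity_class)
  if (mode == "pseudo_time") {
    records$distance <- pseudo_time$distances
    records$pseudo_rank <- match(seq_len(nrow(records)), pseudo_time$order)
  }
  attr(records, "thresholds") <- thresholds
  records
}

#' Select the fine-tuning (focus) set
#'
#' Two rules are provided: `"above_mean_early"` keeps early-stage compounds
#' with pXC50 strictly greater than the mean pXC50 of the early stage (the
#' model-training description); `"region_alpha"` keeps all alpha-region
#' compounds (the regional definition).
#'
#' @param labelled labelled records from [label_dataset()].
#' @param rule focus selection rule.
#' @return subset of `labelled`.
#' @export
focus_set <- function(labelled, rule = c("above_mean_early", "region_alpha")) {
  rule <- match.arg(rule)
  stopifnot(all(c("stage", "region") %in% names(labelled)))
  keep <- if (rule == "region_alpha") {
    labelled$region == "alpha"
  } else {
    early <- labelled$stage == "early"
    early & labelled$pxc50 > mean(labelled$pxc50[early])
  }
  out <- labelled[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("focus set is empty; review thresholds/stage configuration",
         call. = FALSE)
  }
  out
}

#' Directional aSNN between two labelled regions
#'
#' Mean, over the compounds of `region_a`, of each one's maximum Tanimoto
#' similarity to any compound of `region_b` (see [asnn()]).
#'
#' @param labelled labelled records with a `region` column.
#' @param region_a,region_b region names (query and reference).
#' @param radius,nbits Morgan fingerprint configuration.
#' @export
region_asnn <- function(labelled, region_a, region_b, radius = 2, nbits = 2048) {
  a <- labelled$smiles_canonical[labelled$region == region_a]
  b <- labelled$smiles_canonical[labelled$region == region_b]
  if (length(a) == 0 || length(b) == 0) {
    stop("empty region: ", if (length(a) == 0) region_a else region_b,
         call. = FALSE)
  }
  asnn(a, b, radius = radius, nbits = nbits)
}
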