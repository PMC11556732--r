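quadrantLabels <- c(
  i   = "turnover",
  ii  = "synthesis exceeding downstream use",
  iii = "low biosynthesis and low downstream metabolism",
  iv  = "accumulation from reduced downstream metabolism",
  null_call = "no difference between treatments"
)

metricDirection <- function(fc, selected) {
  dir <- integer(length(fc))
  tie <- selected & fc == 0
  if (any(tie))
    warning("metric selected (VIP >= threshold) with fold change exactly 0; ",
            "treated as stable")
  dir[selected & fc > 0] <- 1L
  dir[selected & fc < 0] <- -1L
  dir
}

#' Joint pool-size and enrichment quadrant classification
#'
#' Combines the pool-size and carbon-13 enrichment responses of a
#' metabolite into the four-quadrant turnover/accumulation framework. A
#' metric counts as "high" (+) or "low" (-) only when it is VIP-selected
#' and its fold change has the corresponding sign; unselected metrics are
#' "stable" (0). The mapping over the nine (pool, enrichment) direction
#' states is total:
#' \itemize{
#'   \item quadrant ii (synthesis exceeding downstream use): pool + and
#'     enrichment +;
#'   \item quadrant iv (accumulation from reduced downstream metabolism):
#'     pool + with enrichment 0/-, or pool 0 with enrichment -;
#'   \item quadrant i (turnover): enrichment + with pool 0/-, or pool -
#'     with enrichment 0;
#'   \item quadrant iii (low biosynthesis and low downstream metabolism):
#'     pool - and enrichment -;
#'   \item null_call: both metrics stable.
#' }
#' The off-axis assignments make the classification antisymmetric:
#' swapping treatment labels (negating both fold changes) exchanges
#' i with iv and ii with iii.
#'
#' @param poolFc,enrFc finite fold changes (high vs ambient) in pool size
#'   and enrichment.
#' @param poolSelected,enrSelected logical VIP selections for each metric.
#' @param metaboliteId optional metabolite identifiers.
#' @return data.frame with columns `metabolite`, `pool_fc`,
#'   `pool_selected`, `enr_fc`, `enr_selected`, `quadrant`
#'   (i/ii/iii/iv/null_call) and `label`.
#' @examples
#' classifyQuadrant(0.10, TRUE, 0.0, FALSE)   # glucose-like: quadrant iv
#' classifyQuadrant(0.00, FALSE, 0.46, TRUE)  # glutamine-like: quadrant i
#' @export
classifyQuadrant <- function(poolFc, poolSelected, enrFc, enrSelected,
                             metaboliteId = NULL) {
  k <- length(poolFc)
  stopifnot(length(enrFc) == k, length(poolSelected) == k,
            length(enrSelected) == k)
  if (any(!is.finite(poolFc)) || any(!is.finite(enrFc)))
    stop("fold changes must be finite")
  pd <- metricDirection(poolFc, poolSelected)
  ed <- metricDirection(enrFc, enrSelected)
  quadrant <- character(k)
  quadrant[pd == 1L & ed == 1L] <- "ii"
  quadrant[pd == -1L & ed == -1L] <- "iii"
  quadrant[(pd == 1L & ed <= 0L) | (pd == 0L & ed == -1L)] <- "iv"
  quadrant[(pd <= 0L & ed == 1L) & quadrant == ""] <- "i"
  quadrant[pd == -1L & ed == 0L] <- "i"
  quadrant[pd == 0L & ed == 0L] <- "null_call"
  if (is.null(metaboliteId)) metaboliteId <- paste0("m", seq_len(k))
  data.frame(metabolite = metaboliteId,
             pool_fc = poolFc, pool_selected = poolSelected,
             enr_fc = enrFc, enr_selected = enrSelected,
             quadrant = quadrant,
             label = unname(quadrantLabels[quadrant]),
             row.names = NULL)
}

#' Quadrant calls from pool-size and enrichment VIP tables
#'
#' @param poolVip,enrVip data.frames from [vipFoldChange()] for pool size
#'   and enrichment respectively (columns `metabolite`, `vip`, `selected`,
#'   `fc`). Metabolites present in both tables are classified.
#' @return A quadrant-call data.frame, see [classifyQuadrant()], with the
#'   VIP scores carried along.
#' @export
quadrantCalls <- function(poolVip, enrVip) {
  shared <- intersect(poolVip$metabolite, enrVip$metabolite)
  pv <- poolVip[match(shared, poolVip$metabolite), ]
  ev <- enrVip[match(shared, enrVip$metabolite), ]
  calls <- classifyQuadrant(pv$fc, pv$selected, ev$fc, ev$selected,
                            metaboliteId = shared)
  calls$pool_vip <- pv$vip
  calls$enr_vip <- ev$vip
  calls
}

#' Packaged pathway annotation
#'
#' Metabolite-to-pathway membership for the central carbon and nitrogen
#' pathways analyzed by the pipeline (glycolysis/central carbon, pentose
#' phosphate, TCA cycle, ammonium assimilation, urea cycle, dipeptide
#' production). A metabolite may belong to several pathways (e.g.
#' pyruvate sits in glycolysis and the TCA cycle). Users can pass their
#' own data.frame with the same two columns anywhere an annotation is
#' accepted.
#'
#' @param file optional path to a user CSV with columns `metabolite`,
#'   `pathway`; defaults to the packaged table.
#' @return data.frame with columns `metabolite`, `pathway`.
#' @export
pathwayAnnotations <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "pathways.csv", package = "symbioTrace",
                        mustWork = TRUE)
  ann <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite", "pathway") %in% names(ann)))
  ann
}

#' Per-pathway summary of quadrant calls
#'
#' One row per (metabolite, pathway) pair with direction and percent
#' relative difference for each metric. Percent is `fc * 100` with sign
#' and is omitted (NA) for stable metrics; direction is `"high"` /
#' `"ambient"` / `"stable"` depending on which treatment holds the larger
#' value.
#'
#' @param calls quadrant-call data.frame from [quadrantCalls()] or
#'   [classifyQuadrant()].
#' @param annotations pathway annotation data.frame (default the packaged
#'   one, see [pathwayAnnotations()]).
#' @return data.frame with columns `pathway`, `metabolite`,
#'   `pool_direction`, `pool_percent`, `enr_direction`, `enr_percent`,
#'   `quadrant`. Unannotated metabolites are dropped with a warning.
#' @export
pathwayReport <- function(calls, annotations = pathwayAnnotations()) {
  unknown <- setdiff(calls$metabolite, annotations$metabolite)
  if (length(unknown))
    warning("excluding unannotated metabolite(s): ",
            paste(unknown, collapse = ", "))
  merged <- merge(annotations, calls, by = "metabolite")
  direction <- function(fc, sel)
    ifelse(!sel | fc == 0, "stable", ifelse(fc > 0, "high", "ambient"))
  pct <- function(fc, sel) ifelse(!sel | fc == 0, NA_real_, fc * 100)
  out <- data.frame(
    pathway = merged$pathway,
    metabolite = merged$metabolite,
    pool_direction = direction(merged$pool_fc, merged$pool_selected),
    pool_percent = pct(merged$pool_fc, merged$pool_selected),
    enr_direction = direction(merged$enr_fc, merged$enr_selected),
    enr_percent = pct(merged$enr_fc, merged$enr_selected),
    quadrant = merged$quadrant,
    row.names = NULL)
  out[order(out$pathway, out$metabolite), ]
}
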