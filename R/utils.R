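## Internal helpers shared across modules.

#' @importFrom methods is new validObject
#' @importFrom stats median pchisq pt phyper p.adjust rbinom rnbinom runif
#'   shapiro.test setNames sd rnorm
#' @importFrom utils read.delim write.table head
NULL

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.checkCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) ||
      x < min)
    .stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

.checkProb <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    .stopf("'%s' must be a single value in [0, 1]", name)
  as.numeric(x)
}

## Deterministic 32-bit polynomial string hash (used to derive unigene ids
## from annotation strings; stability across sessions matters, randomness
## does not).
.stringHash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (i in utf8ToInt(enc2utf8(s))) h <- (h * 31 + i) %% 2147483647
    sprintf("%08x", as.integer(h))
  }, character(1), USE.NAMES = FALSE)
}

#' Treatment label for an origin/destination pair
#'
#' Treatments are labelled `"<origin>-><destination>"`, e.g. `"400->1550"`
#' for animals raised at 400 uatm pCO2 and transplanted to 1550 uatm.
#'
#' @param origin,destination numeric pCO2 levels (uatm).
#' @return character vector of treatment labels.
#' @export
treatmentLabel <- function(origin, destination) {
  paste0(format(origin, trim = TRUE, scientific = FALSE), "->",
         format(destination, trim = TRUE, scientific = FALSE))
}

.designColumns <- c("sample_id", "origin_pco2", "destination_pco2",
                    "replicate", "pool_size")

## Validate a sample design table; returns it with canonical column types.
.validateDesign <- function(design, context = "design") {
  if (!is.data.frame(design))
    .stopf("%s must be a data.frame", context)
  miss <- setdiff(.designColumns, colnames(design))
  if (length(miss))
    .stopf("%s is missing column(s): %s", context, paste(miss, collapse = ", "))
  design <- as.data.frame(design)[, .designColumns]
  design$sample_id <- as.character(design$sample_id)
  design$replicate <- as.character(design$replicate)
  design$origin_pco2 <- as.numeric(design$origin_pco2)
  design$destination_pco2 <- as.numeric(design$destination_pco2)
  design$pool_size <- as.integer(design$pool_size)
  if (anyDuplicated(design$sample_id))
    .stopf("%s contains duplicated sample_id(s): %s", context,
           paste(unique(design$sample_id[duplicated(design$sample_id)]),
                 collapse = ", "))
  if (any(!is.finite(design$origin_pco2)) ||
      any(!is.finite(design$destination_pco2)))
    .stopf("%s has non-finite pCO2 values", context)
  if (any(is.na(design$pool_size)) || any(design$pool_size < 1L))
    .stopf("%s has pool_size < 1", context)
  design
}

## The three pCO2 levels (low, mid, high) used by the reciprocal-transplant
## layout, derived from the origins present in the design.
.pco2Levels <- function(design) {
  lev <- sort(unique(c(design$origin_pco2, design$destination_pco2)))
  if (length(lev) != 3L)
    .stopf("design must span exactly 3 pCO2 levels, found %d: %s",
           length(lev), paste(lev, collapse = ", "))
  names(lev) <- c("low", "mid", "high")
  lev
}

## The seven reciprocal-transplant treatments, in canonical order.
.transplantTreatments <- function(levels) {
  lo <- levels[["low"]]; mi <- levels[["mid"]]; hi <- levels[["high"]]
  data.frame(
    origin = c(lo, mi, hi, lo, lo, mi, hi),
    destination = c(lo, mi, hi, mi, hi, lo, lo)
  )
}

## Indices of design rows for one treatment; errors if absent.
.treatmentSamples <- function(design, origin, destination) {
  idx <- which(design$origin_pco2 == origin &
               design$destination_pco2 == destination)
  if (!length(idx))
    .stopf("design has no sample for treatment %s",
           treatmentLabel(origin, destination))
  idx
}

## Check that the design contains all 7 transplant treatments; returns the
## level vector.
.checkFullDesign <- function(design) {
  lev <- .pco2Levels(design)
  tr <- .transplantTreatments(lev)
  for (i in seq_len(nrow(tr)))
    .treatmentSamples(design, tr$origin[i], tr$destination[i])
  lev
}

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- .checkCount(seed, "seed", min = 0L)
    set.seed(seed)
  }
  expr
}
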