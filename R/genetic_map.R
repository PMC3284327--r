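#' Convert genetic distance to recombination fraction
#'
#' Map functions translating an interval's genetic length d (in cM) into
#' the meiotic recombination fraction r used throughout the package:
#' Haldane (no interference), r = (1 - exp(-2d/100))/2, or Kosambi,
#' r = tanh(2d/100)/2.
#'
#' @param d_cM Genetic distance(s) in centiMorgans (>= 0).
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' map_to_recfrac(10)  # 0.09063...
#' @export
map_to_recfrac <- function(d_cM, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(d_cM < 0)) stop("genetic distances must be non-negative")
  d <- d_cM / 100
  switch(map_function,
         haldane = (1 - exp(-2 * d)) / 2,
         kosambi = tanh(2 * d) / 2)
}

#' Read a genetic map and derive interval recombination fractions
#'
#' Reads a CSV with columns `marker`, `chromosome` and `position_cM` (the
#' column `position` is also accepted) and converts the distances between
#' adjacent markers within each chromosome into recombination fractions via
#' the chosen map function.
#'
#' @param path Path to the CSV file.
#' @param map_function Passed to [map_to_recfrac()].
#' @return A data frame with one row per marker interval: `chromosome`,
#'   `marker_left`, `marker_right`, `d_cM`, `r`.
#' @export
read_genetic_map <- function(path, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  mp <- utils::read.csv(path, stringsAsFactors = FALSE)
  poscol <- intersect(c("position_cM", "position"), names(mp))[1]
  if (!all(c("marker", "chromosome") %in% names(mp)) || is.na(poscol))
    stop("genetic map must have columns marker, chromosome, position_cM")
  if (anyDuplicated(mp$marker)) {
    dup <- mp$marker[duplicated(mp$marker)][1]
    stop("duplicate marker in genetic map: ", dup)
  }
  pos <- as.numeric(mp[[poscol]])
  if (anyNA(pos)) stop("non-numeric marker positions in genetic map")
  out <- do.call(rbind, lapply(split(seq_len(nrow(mp)), mp$chromosome),
                               function(idx) {
    if (length(idx) < 2L) return(NULL)
    p <- pos[idx]
    bad <- which(diff(p) < 0)
    if (length(bad) > 0L)
      stop("marker positions not non-decreasing at marker ",
           mp$marker[idx[bad[1] + 1L]], " (line ", idx[bad[1] + 1L] + 1L,
           " of ", path, ")")
    data.frame(chromosome = mp$chromosome[idx[-length(idx)]],
               marker_left = mp$marker[idx[-length(idx)]],
               marker_right = mp$marker[idx[-1L]],
               d_cM = diff(p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$r <- map_to_recfrac(out$d_cM, map_function)
  out
}
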