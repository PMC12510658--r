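# Time-course dataset container and CSV I/O.

.ppi_observed_species <- c("PI", "PI4P", "PIP2", "PIP3", "PI34P2", "IP1")

#' Observed species labels
#'
#' The six experimentally measured pools: the five lipids PtdIns (`PI`),
#' PtdIns4P (`PI4P`), PtdIns(4,5)P2 (`PIP2`), PtdIns(3,4,5)P3 (`PIP3`),
#' PtdIns(3,4)P2 (`PI34P2`) by ion chromatography-mass spectrometry, and the
#' soluble inositol monophosphate `IP1` by ELISA.
#' @return Character vector of length 6.
#' @export
ppi_species <- function() .ppi_observed_species

#' Construct a time-course dataset
#'
#' @param replicates Data frame with columns `time_s`, `species`,
#'   `replicate`, `value` (molecules per platelet).
#' @param truth Optional list recording the generating model and parameters
#'   (for recovery scoring on synthetic data).
#' @return Object of class `ppi_data`: the replicate records plus a
#'   per-(time, species) mean view (`means`, wide matrix time x species).
#' @export
ppi_data <- function(replicates, truth = NULL) {
  need <- c("time_s", "species", "replicate", "value")
  missing <- setdiff(need, names(replicates))
  if (length(missing))
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "))
  replicates <- replicates[need]
  bad <- setdiff(unique(replicates$species), .ppi_observed_species)
  if (length(bad))
    stop("unknown species label(s): ", paste(bad, collapse = ", "))
  absent <- setdiff(.ppi_observed_species, unique(replicates$species))
  if (length(absent))
    stop("species absent from dataset: ", paste(absent, collapse = ", "))
  if (any(replicates$value < 0))
    stop("abundances must be non-negative")
  key <- paste(replicates$time_s, replicates$species, replicates$replicate)
  if (anyDuplicated(key))
    stop("duplicate (time, species, replicate) rows")
  times <- sort(unique(replicates$time_s))
  means <- tapply(replicates$value,
                  list(factor(replicates$time_s, levels = times),
                       factor(replicates$species,
                              levels = .ppi_observed_species)),
                  mean)
  means <- matrix(as.numeric(means), nrow = length(times),
                  dimnames = list(NULL, .ppi_observed_species))
  structure(list(replicates = replicates, means = means, times = times,
                 species = .ppi_observed_species, truth = truth),
            class = "ppi_data")
}

#' @export
print.ppi_data <- function(x, ...) {
  cat("ppi_data:", nrow(x$replicates), "measurements,",
      length(x$times), "timepoints x", length(x$species), "species,",
      max(x$replicates$replicate), "replicate(s)\n")
  if (!is.null(x$truth))
    cat("  synthetic; generated from", x$truth$variant, "\n")
  cat("  mean view (molecules/platelet):\n")
  m <- cbind(time_s = x$times, signif(x$means, 3))
  print(utils::head(as.data.frame(m), 7))
  invisible(x)
}

#' @export
as.data.frame.ppi_data <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  x$replicates
}

# mean view as long data.frame
.ppi_mean_long <- function(x) {
  data.frame(time_s = rep(x$times, times = ncol(x$means)),
             species = rep(colnames(x$means), each = length(x$times)),
             value = as.vector(x$means), stringsAsFactors = FALSE)
}

#' Read / write time-course CSV
#'
#' Tidy long format with header `time_s, species, replicate, value`; time in
#' seconds, value in molecules per platelet, species from [ppi_species()].
#'
#' @param path CSV file path.
#' @return `ppi_read_timecourse` returns a [ppi_data()] object.
#' @export
ppi_read_timecourse <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ppi_data(df)
}

#' @rdname ppi_read_timecourse
#' @param data `ppi_data` object.
#' @export
ppi_write_timecourse <- function(data, path) {
  stopifnot(inherits(data, "ppi_data"))
  write.csv(data$replicates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
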