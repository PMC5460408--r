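#' @include synthetic-data.R
NULL

## 17-significant-digit decimal strings round-trip IEEE doubles exactly.
.numToStr <- function(x) sprintf("%.17g", x)

.designToList <- function(d) {
  list(strain = strainLabel(d@strain),
       hxt = as.list(transporterFlags(d@strain)),
       pre_mM = d@profile@preLevel, post_mM = d@profile@postLevel,
       shift_min = d@profile@shiftTime,
       n_cells = if (is.character(d@nCells)) d@nCells else
         as.integer(d@nCells),
       sampling_interval_min = d@samplingInterval,
       pre_time_min = d@preTime, duration_min = d@duration,
       noise_cv = d@noiseCv, size_mean = d@sizeMean, size_sd = d@sizeSd,
       size_effect = d@sizeEffect, seed = d@seed)
}

.designFromList <- function(l) {
  strain <- strainConfig(l$strain, l$hxt$hxt1a, l$hxt$hxt4a, l$hxt$hxt7a)
  d <- experimentDesign(strain = strain, postLevel = l$post_mM,
                        nCells = if (is.character(l$n_cells)) l$n_cells
                        else as.integer(l$n_cells),
                        samplingInterval = l$sampling_interval_min,
                        preTime = l$pre_time_min,
                        duration = l$duration_min, noiseCv = l$noise_cv,
                        sizeMean = l$size_mean, sizeSd = l$size_sd,
                        sizeEffect = l$size_effect,
                        seed = as.integer(l$seed))
  d@profile <- glucoseProfile(l$post_mM, l$pre_mM, l$shift_min)
  d
}

#' Write and read trace sets
#'
#' The interchange format is a tidy CSV with columns \code{cell_id},
#' \code{time_min}, \code{ratio}, \code{size_au}, \code{strain},
#' \code{gex_mM} (one row per cell and time point) plus, for synthetic
#' sets, a JSON provenance sidecar (same path with extension
#' \code{.json}) carrying the design, the master seed, the fixed
#' effects, the random-effect covariance, the per-cell \code{theta} and
#' \code{eta} and the noise-free ratios.  Numeric fields are written at
#' full double precision so write-then-read is the identity.  Reading a
#' CSV without a sidecar yields an observational trace set (no ground
#' truth).
#'
#' @param traces a \linkS4class{TraceSet}.
#' @param path CSV file path.
#' @return \code{writeTraces} invisibly returns \code{path};
#'   \code{readTraces} returns a \linkS4class{TraceSet}.
#' @export
writeTraces <- function(traces, path) {
  stopifnot(is(traces, "TraceSet"))
  df <- as.data.frame(traces)
  out <- data.frame(cell_id = df$cell_id,
                    time_min = .numToStr(df$time_min),
                    ratio = .numToStr(df$ratio),
                    size_au = .numToStr(df$size_au),
                    strain = df$strain,
                    gex_mM = .numToStr(df$gex_mM))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (isSynthetic(traces)) {
    md <- S4Vectors::metadata(traces)
    side <- list(
      synthetic = TRUE, seed = md$seed,
      design = if (!is.null(md$design)) .designToList(md$design),
      pre_mM = md$profile@preLevel, shift_min = md$profile@shiftTime,
      theta_bar = as.list(parameterVector(md$thetaBar)),
      covariance = md$covariance,
      cell_id = colnames(traces),
      theta = md$theta, eta = md$eta,
      true_ratio = trueRatios(traces))
    jsonlite::write_json(side, .sidecarPath(path), digits = I(17),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

.sidecarPath <- function(path)
  paste0(tools::file_path_sans_ext(path), ".json")

#' @rdname writeTraces
#' @export
readTraces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_min", "ratio", "size_au", "strain", "gex_mM")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("malformed trace CSV: missing column(s) ",
         paste(miss, collapse = ", "))
  for (col in c("time_min", "ratio", "size_au", "gex_mM")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("malformed trace CSV: non-numeric '%s' at row %d",
                   col, bad[1L]))
    df[[col]] <- v
  }
  bad <- which(df$ratio <= 0)
  if (length(bad))
    stop(sprintf("invalid trace CSV: non-positive ratio at row %d, column 'ratio'",
                 bad[1L]))
  cells <- unique(df$cell_id)
  tm <- sort(unique(df$time_min))
  if (nrow(df) != length(cells) * length(tm))
    stop("malformed trace CSV: cells do not share one time grid")
  df <- df[order(match(df$cell_id, cells), df$time_min), ]
  ratio <- matrix(df$ratio, nrow = length(tm), ncol = length(cells))
  size <- df$size_au[match(cells, df$cell_id)]
  strainLab <- unique(df$strain)
  post <- unique(df$gex_mM)
  if (length(strainLab) != 1L || length(post) != 1L)
    stop("trace CSV must describe a single experiment (one strain, one upshift)")

  side <- .sidecarPath(path)
  if (file.exists(side)) {
    md <- jsonlite::fromJSON(side)
    strain <- if (!is.null(md$design))
      strainConfig(md$design$strain, md$design$hxt$hxt1a,
                   md$design$hxt$hxt4a, md$design$hxt$hxt7a)
    else strainConfig(strainLab)
    profile <- glucoseProfile(post, md$pre_mM, md$shift_min)
    theta <- md$theta; eta <- md$eta; true <- md$true_ratio
    dimnames(theta) <- dimnames(eta) <- list(.PARAM_NAMES, md$cell_id)
    TraceSet(ratio = ratio, time = tm, cellId = cells, size = size,
             strain = strain, profile = profile, trueRatio = true,
             theta = theta, eta = eta,
             thetaBar = modelParameters(unlist(md$theta_bar)),
             covariance = validateCovariance(md$covariance),
             design = if (!is.null(md$design)) .designFromList(md$design),
             seed = as.integer(md$seed), synthetic = TRUE)
  } else {
    TraceSet(ratio = ratio, time = tm, cellId = cells, size = size,
             strain = strainConfig(strainLab,
                                   hxt1a = as.integer(strainLab == "WT" |
                                                        strainLab == "HXT1"),
                                   hxt4a = as.integer(strainLab == "WT"),
                                   hxt7a = as.integer(strainLab == "WT" |
                                                        strainLab == "HXT7")),
             profile = glucoseProfile(post), synthetic = FALSE)
  }
}
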