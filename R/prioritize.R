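#' Construct a grid layer
#'
#' A minimal co-registered raster: a numeric matrix (row 1 = northernmost
#' row), missing cells as `NA`, and cell-center registration metadata.
#'
#' @param values numeric matrix with `NA` for nodata cells; finite values
#'   must be non-negative.
#' @param xll,yll coordinates of the lower-left corner.
#' @param cellsize cell size (square cells).
#' @return an object of class `grid_layer`.
#' @export
grid_layer <- function(values, xll = 0, yll = 0, cellsize = 1) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(values < 0, na.rm = TRUE))
    stop("grid values must be non-negative", call. = FALSE)
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "grid_layer")
}

#' @keywords internal
check_registration <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(c(a$xll, a$yll, a$cellsize),
                        c(b$xll, b$yll, b$cellsize))))
    stop("grid layers are not co-registered (shape/origin/cellsize differ); ",
         "resample before analysis", call. = FALSE)
}

#' Crop benefit index: woody share of total production
#'
#' Cellwise `woody / total`.  Cells with zero total production become missing
#' (oceans and no-crop land are not zero-benefit cells and must not compress
#' the terciles).
#'
#' @param woody,total co-registered `grid_layer`s of woody and total crop
#'   production.
#' @return a `grid_layer` of proportions in [0, 1].
#' @export
benefit_index <- function(woody, total) {
  check_registration(woody, total)
  w <- woody$values; t <- total$values
  bad <- which(!is.na(w) & !is.na(t) & w > t + 1e-9)
  if (length(bad))
    stop("woody production exceeds total production at cell(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  out <- w / t
  out[!is.na(t) & t == 0] <- NA
  out[is.na(w) | is.na(t)] <- NA
  grid_layer(out, woody$xll, woody$yll, woody$cellsize)
}

#' Min-max standardization of a grid layer to [0, 1]
#'
#' `(x - min) / (max - min)` over non-missing cells.  A constant layer maps
#' to all 0 with a warning so downstream products remain defined.
#'
#' @param layer a `grid_layer`.
#' @return a `grid_layer` with values in [0, 1].
#' @export
standardize_minmax <- function(layer) {
  x <- layer$values
  stopifnot(any(!is.na(x)))
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) {
    warning("constant layer: standardized values set to 0")
    out <- ifelse(is.na(x), NA, 0)
  } else {
    out <- (x - rng[1]) / (rng[2] - rng[1])
  }
  grid_layer(out, layer$xll, layer$yll, layer$cellsize)
}

#' Integrative conservation value index
#'
#' Min-max standardizes each richness layer and multiplies them cellwise, so
#' a cell is valuable when both the richness of threatened bird species and
#' the richness of all bird species are high.
#'
#' @param threatened_richness,total_richness co-registered `grid_layer`s.
#' @return a `grid_layer` of products in [0, 1].
#' @export
integrative_index <- function(threatened_richness, total_richness) {
  check_registration(threatened_richness, total_richness)
  a <- standardize_minmax(threatened_richness)
  b <- standardize_minmax(total_richness)
  grid_layer(a$values * b$values, a$xll, a$yll, a$cellsize)
}

#' Tercile classification of a grid layer
#'
#' Cuts the non-missing cells at their 1/3 and 2/3 quantiles (linear
#' interpolation); code 3 is the top tercile and boundary ties go to the
#' lower class.
#'
#' @param layer a `grid_layer`.
#' @return integer matrix of codes 1-3 (`NA` where the input is missing).
#' @export
tercile_classify <- function(layer) {
  x <- layer$values
  ok <- !is.na(x)
  stopifnot(sum(ok) >= 3)
  if (diff(range(x[ok])) == 0) {
    warning("constant layer: all cells assigned to tercile 1")
    out <- ifelse(ok, 1L, NA_integer_)
    dim(out) <- dim(x)
    return(out)
  }
  qs <- stats::quantile(x[ok], c(1, 2) / 3, type = 7, names = FALSE)
  out <- ifelse(!ok, NA_integer_,
                ifelse(x <= qs[1], 1L, ifelse(x <= qs[2], 2L, 3L)))
  dim(out) <- dim(x)
  out
}

#' Bivariate tercile classification and priority mask
#'
#' Crosses the terciles of the crop benefit index and a conservation value
#' index into a 3x3 class grid
#' (`class = 3 (conservation tercile - 1) + benefit tercile`, so class 9 is
#' top tercile in both) and marks the joint top-tercile cells as priority
#' areas.  Cells missing in either input are missing everywhere.
#'
#' @param benefit,conservation co-registered `grid_layer`s.
#' @return an object of class `bivariate_class_grid`: list with `class`
#'   (integer matrix 1-9), `priority` (logical matrix), `benefit_tercile`,
#'   `conservation_tercile` and a `legend` data frame.
#' @export
priority_mask <- function(benefit, conservation) {
  check_registration(benefit, conservation)
  miss <- is.na(benefit$values) | is.na(conservation$values)
  b <- benefit; b$values[miss] <- NA
  c_ <- conservation; c_$values[miss] <- NA
  tb <- tercile_classify(b)
  tc <- tercile_classify(c_)
  cls <- 3L * (tc - 1L) + tb
  pri <- !is.na(cls) & tb == 3L & tc == 3L
  legend <- expand.grid(benefit_tercile = 1:3, conservation_tercile = 1:3)
  legend$class <- 3L * (legend$conservation_tercile - 1L) + legend$benefit_tercile
  legend$priority <- legend$class == 9L
  structure(list(class = cls, priority = pri,
                 benefit_tercile = tb, conservation_tercile = tc,
                 legend = legend[order(legend$class), ]),
            class = "bivariate_class_grid")
}

#' Read an ESRI ASCII grid
#'
#' @param path path to an `.asc` file.
#' @return a `grid_layer`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ASCII grid header lacks: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  grid_layer(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
             cellsize = hdr$cellsize)
}

#' Write a grid layer as an ESRI ASCII grid
#'
#' @param layer a `grid_layer` (or an integer/logical matrix plus the
#'   registration of a template layer via `template`).
#' @param path output path.
#' @param nodata value written for missing cells.
#' @param template optional `grid_layer` supplying registration when `layer`
#'   is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999, template = NULL) {
  if (is.matrix(layer)) {
    stopifnot(!is.null(template))
    layer <- list(values = layer + 0, xll = template$xll, yll = template$yll,
                  cellsize = template$cellsize)
  }
  m <- layer$values
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", layer$xll), paste("yllcorner", layer$yll),
           paste("cellsize", layer$cellsize),
           paste("NODATA_value", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
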