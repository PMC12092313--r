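# data_pipeline module: manifest loading, centre cropping, patient-level
# splitting, and the x10 affine augmentation of the training partition.

.readSliceFile <- function(path, sliceIndex = NA, cache = NULL) {
  if (!file.exists(path)) stop("cannot read slice file '", path, "'")
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- if (!is.null(cache) && !is.null(cache[[path]])) cache[[path]]
      else {
        v <- as.array(RNifti::readNifti(path))
        if (!is.null(cache)) cache[[path]] <- v
        v
      }
    if (length(dim(vol)) == 2L) {
      if (!is.na(sliceIndex) && sliceIndex != 1)
        stop("2D NIfTI '", path, "' has no slice ", sliceIndex)
      return(vol)
    }
    if (is.na(sliceIndex))
      stop("NIfTI volume '", path, "' needs a slice_index")
    if (sliceIndex < 1 || sliceIndex > dim(vol)[3])
      stop("slice_index ", sliceIndex, " out of range for '", path, "'")
    return(vol[, , sliceIndex])
  }
  img <- if (grepl("\\.png$", lower)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF slices requires the 'tiff' package")
    tiff::readTIFF(path)
  } else stop("unsupported slice format: '", path, "'")
  if (length(dim(img)) == 3L) img <- img[, , 1]   # collapse to grayscale
  if (length(dim(img)) != 2L)
    stop("slice '", path, "' is not a 2D raster")
  img
}

#' Load a slice dataset from a manifest
#'
#' The manifest is a CSV (or data.frame) with columns subject_id, label,
#' path and slice_index (empty for 2D slice files), plus an optional
#' partition column. Slices may be NIfTI volumes (indexed by slice_index)
#' or per-slice PNG/TIFF rasters. Labels are validated against the fixed
#' AL/ATTR/CTRL vocabulary; intensities are kept exactly as stored (no
#' rescaling) -- NIfTI and float-TIFF preserve SUV-like real values, while
#' PNG slices arrive on the [0, 1] scale of the png reader.
#'
#' @param manifest Path to a manifest CSV, or an equivalent data.frame.
#' @param baseDir Directory against which relative slice paths are
#'   resolved; defaults to the manifest's directory.
#' @return A \linkS4class{SubjectDataset}.
#' @export
loadDataset <- function(manifest, baseDir = NULL) {
  if (is.character(manifest)) {
    if (is.null(baseDir)) baseDir <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(baseDir)) baseDir <- "."
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(manifest)))
    stop("loadDataset: manifest needs columns ",
         paste(need, collapse = ", "))
  if (!nrow(manifest)) {
    warning("loadDataset: empty manifest", call. = FALSE)
    return(new("SubjectDataset", subjects = list()))
  }
  if (is.null(manifest$slice_index)) manifest$slice_index <- NA
  if (is.null(manifest$partition)) manifest$partition <- "unassigned"
  cache <- new.env(parent = emptyenv())
  subjects <- list()
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    if (!row$label %in% classLabels())
      stop("loadDataset: row ", r, ": unknown label '", row$label, "'")
    path <- if (file.exists(row$path)) row$path else file.path(baseDir, row$path)
    slice <- tryCatch(
      .readSliceFile(path, suppressWarnings(as.numeric(row$slice_index)),
                     cache),
      error = function(e) stop("loadDataset: row ", r, ": ",
                               conditionMessage(e)))
    sid <- as.character(row$subject_id)
    if (is.null(subjects[[sid]])) {
      subjects[[sid]] <- list(subject_id = sid, label = row$label,
                              slices = list(),
                              partition = as.character(row$partition))
    } else {
      if (subjects[[sid]]$label != row$label)
        stop("loadDataset: row ", r, ": subject ", sid,
             " has conflicting labels")
      if (subjects[[sid]]$partition != row$partition)
        stop("loadDataset: row ", r, ": subject ", sid,
             " has conflicting partitions")
    }
    subjects[[sid]]$slices <- c(subjects[[sid]]$slices, list(slice))
  }
  new("SubjectDataset", subjects = unname(subjects))
}

#' Centre-crop a slice
#'
#' @param image 2D numeric matrix, at least target-sized.
#' @param target Target (rows, cols); default c(77, 104).
#' @return The centre crop; intensities untouched.
#' @export
#' @examples
#' dim(cropSlice(matrix(0, 128, 128)))
cropSlice <- function(image, target = c(77, 104)) {
  d <- dim(image)
  if (is.null(d) || length(d) != 2L)
    stop("cropSlice: image must be a 2D matrix")
  if (d[1] < target[1] || d[2] < target[2])
    stop("cropSlice: image ", d[1], "x", d[2],
         " smaller than target ", target[1], "x", target[2])
  r0 <- (d[1] - target[1]) %/% 2L
  c0 <- (d[2] - target[2]) %/% 2L
  image[(r0 + 1L):(r0 + target[1]), (c0 + 1L):(c0 + target[2])]
}

#' Apply a function to every slice of a dataset
#'
#' @param dataset A \linkS4class{SubjectDataset}.
#' @param f Function(matrix) -> matrix, e.g.
#'   \code{function(s) cropSlice(s, c(77, 104))}.
#' @return The transformed dataset.
#' @export
mapSlices <- function(dataset, f) {
  dataset@subjects <- lapply(dataset@subjects, function(s) {
    s$slices <- lapply(s$slices, f)
    s
  })
  dataset
}

#' Partition a dataset at the patient level
#'
#' Every subject is placed wholly inside one partition, so no subject
#' contributes slices to more than one of train/validation/test. Either an
#' explicit assignment (named character vector subject_id -> partition) or
#' per-class subject counts for the test and validation partitions are
#' given; remaining subjects go to train. Sampling uses the current RNG
#' state.
#'
#' @param dataset A \linkS4class{SubjectDataset}.
#' @param assignment Optional named character vector mapping subject ids to
#'   partitions; overrides the count-based interface.
#' @param testCounts,valCounts Named per-class subject counts, e.g.
#'   \code{c(AL = 3, ATTR = 3, CTRL = 5)}.
#' @return The dataset with partitions assigned.
#' @export
splitByPatient <- function(dataset, assignment = NULL,
                           testCounts = NULL, valCounts = NULL) {
  ids <- subjectIds(dataset)
  labels <- subjectLabels(dataset)
  if (is.null(assignment)) {
    assignment <- stats::setNames(rep("train", length(ids)), ids)
    for (part in c("test", "val")) {
      counts <- if (part == "test") testCounts else valCounts
      if (is.null(counts)) next
      for (cl in names(counts)) {
        avail <- ids[labels == cl & assignment[ids] == "train"]
        if (length(avail) < counts[[cl]])
          stop("splitByPatient: requested ", counts[[cl]], " ", cl,
               " subjects for ", part, " but only ", length(avail),
               " available")
        pick <- if (length(avail) == 1L) avail else
          sample(avail, counts[[cl]])
        assignment[pick] <- part
      }
    }
  }
  missing <- setdiff(ids, names(assignment))
  if (length(missing))
    stop("splitByPatient: no assignment for subjects ",
         paste(missing, collapse = ", "))
  dataset@subjects <- lapply(dataset@subjects, function(s) {
    p <- assignment[[s$subject_id]]
    if (!p %in% c("train", "val", "test", "unassigned"))
      stop("splitByPatient: bad partition '", p, "' for subject ",
           s$subject_id)
    s$partition <- p
    s
  })
  validObject(dataset)
  dataset
}

#' Re-split the non-test subjects into train/validation
#'
#' Keeps the test partition fixed (the k-fold protocol) and redraws which
#' non-test subjects serve as validation, per class. If a drawn validation
#' side would miss a class present in the data the draw is resampled (with
#' a log message).
#'
#' @param dataset A partitioned \linkS4class{SubjectDataset}.
#' @param valCounts Named per-class subject counts for validation.
#' @return The re-partitioned dataset.
#' @export
resplitTrainVal <- function(dataset, valCounts) {
  ids <- subjectIds(dataset)
  labels <- subjectLabels(dataset)
  parts <- subjectPartitions(dataset)
  nonTest <- ids[parts != "test"]
  for (attempt in 1:100) {
    assignment <- stats::setNames(parts, ids)
    assignment[nonTest] <- "train"
    ok <- TRUE
    for (cl in names(valCounts)) {
      avail <- nonTest[labels[match(nonTest, ids)] == cl]
      if (length(avail) <= valCounts[[cl]]) { ok <- FALSE; break }
      pick <- if (length(avail) == 1L) avail else sample(avail, valCounts[[cl]])
      assignment[pick] <- "val"
    }
    if (!ok)
      stop("resplitTrainVal: infeasible valCounts for available subjects")
    trainLabels <- labels[assignment[ids] == "train"]
    if (all(unique(labels) %in% trainLabels)) {
      dataset@subjects <- lapply(dataset@subjects, function(s) {
        s$partition <- assignment[[s$subject_id]]
        s
      })
      return(dataset)
    }
    message("resplitTrainVal: a class missing from training side; resampling")
  }
  stop("resplitTrainVal: could not produce a split with all classes in train")
}

#' Construct an affine augmentation policy
#'
#' Each augmented copy draws a translation uniform in [-maxTranslation,
#' +maxTranslation] pixels per axis and a rotation uniform in
#' [-maxRotation, +maxRotation] degrees; out-of-frame regions are filled
#' with `fill`.
#'
#' @param copiesPerImage Copies per training image (default 10).
#' @param maxTranslation Maximum |dx|, |dy| in pixels (default 10).
#' @param maxRotation Maximum |angle| in degrees (default 10).
#' @param fill Fill value for out-of-frame pixels (default 0).
#' @return List of class "evonas_policy".
#' @export
augmentationPolicy <- function(copiesPerImage = 10, maxTranslation = 10,
                               maxRotation = 10, fill = 0) {
  structure(list(copiesPerImage = as.integer(copiesPerImage),
                 maxTranslation = maxTranslation,
                 maxRotation = maxRotation, fill = fill),
            class = "evonas_policy")
}

#' Affine transform of a slice (rotate about centre, then translate)
#'
#' Rotates the image about its centre by `angle` degrees
#' (counter-clockwise in row/col coordinates), then translates by dx
#' columns and dy rows. The output has the same dimensions; resampling is
#' bilinear via inverse mapping; pixels mapped from outside the frame take
#' the fill value. When a policy is supplied, parameters outside its bounds
#' are rejected.
#'
#' @param image 2D numeric matrix.
#' @param dx,dy Translation in pixels (columns, rows).
#' @param angle Rotation in degrees.
#' @param fill Fill value.
#' @param policy Optional \code{\link{augmentationPolicy}} whose bounds are
#'   enforced.
#' @return Transformed matrix of the same dimensions.
#' @export
#' @examples
#' img <- matrix(0, 9, 9); img[5, 5] <- 1
#' moved <- affineTransform(img, dx = 2, dy = 1, angle = 0)
#' which(moved == 1, arr.ind = TRUE)   # row 6, col 7
affineTransform <- function(image, dx, dy, angle, fill = 0, policy = NULL) {
  if (!is.null(policy)) {
    if (abs(dx) > policy$maxTranslation || abs(dy) > policy$maxTranslation)
      stop("affineTransform: translation (", dx, ", ", dy,
           ") exceeds policy bound ", policy$maxTranslation)
    if (abs(angle) > policy$maxRotation)
      stop("affineTransform: rotation ", angle,
           " exceeds policy bound ", policy$maxRotation)
  }
  d <- dim(image)
  H <- d[1]; W <- d[2]
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  th <- angle * pi / 180
  co <- cos(th); si <- sin(th)
  # inverse map: undo translation, then rotate by -angle about the centre
  og <- expand.grid(r = seq_len(H), c = seq_len(W))
  rr <- og$r - dy - cr
  cc2 <- og$c - dx - cc
  srcR <- co * rr + si * cc2 + cr
  srcC <- -si * rr + co * cc2 + cc
  r0 <- floor(srcR); c0 <- floor(srcC)
  fr <- srcR - r0; fc <- srcC - c0
  pick <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- rep(fill, length(ri))
    v[ok] <- image[cbind(ri[ok], ci[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * pick(r0, c0) +
       (1 - fr) * fc * pick(r0, c0 + 1) +
       fr * (1 - fc) * pick(r0 + 1, c0) +
       fr * fc * pick(r0 + 1, c0 + 1)
  matrix(v, H, W)
}

#' Augment the training partition (one-time, x copiesPerImage)
#'
#' Replaces every training-partition slice by `copiesPerImage` transformed
#' copies with independently drawn parameters (uniform within the policy
#' bounds; the current RNG state drives the draws). Validation and test
#' slices are untouched; augmented slices inherit their subject id and
#' label.
#'
#' @param dataset A partitioned \linkS4class{SubjectDataset}.
#' @param policy An \code{\link{augmentationPolicy}}.
#' @return The augmented dataset.
#' @export
augmentTrainingSet <- function(dataset, policy = augmentationPolicy()) {
  dataset@subjects <- lapply(dataset@subjects, function(s) {
    if (s$partition != "train") return(s)
    out <- list()
    for (sl in s$slices) {
      for (i in seq_len(policy$copiesPerImage)) {
        dx <- runif(1, -policy$maxTranslation, policy$maxTranslation)
        dy <- runif(1, -policy$maxTranslation, policy$maxTranslation)
        ang <- runif(1, -policy$maxRotation, policy$maxRotation)
        out <- c(out, list(affineTransform(sl, dx, dy, ang,
                                           fill = policy$fill)))
      }
    }
    s$slices <- out
    s
  })
  dataset
}
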