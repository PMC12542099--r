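#' Tissue-segmentation images
#'
#' A TS-image is a tile-resolution label map of a slide: one integer
#' compartment code per tile. Codes are 0 excluded, 1 tumor, 2 stroma,
#' 3 necrosis, 4 iTIL (intratumoral lymphocytes), 5 sTIL (stromal
#' lymphocytes).
#'
#' @name ts_image_module
NULL

#' Label codes of a TS-image
#' @return Named integer vector mapping compartment name to code.
#' @export
ts_codes <- function() {
  c(excluded = 0L, tumor = 1L, stroma = 2L, necrosis = 3L,
    itil = 4L, stil = 5L)
}

#' Construct a TS-image from a label matrix
#'
#' @param labels Integer matrix of compartment codes (see [ts_codes()]).
#' @param patient_id Identifier string.
#' @return Object of class `ts_image` with fields `labels`, `patient_id`.
#' @export
ts_image <- function(labels, patient_id = "unknown") {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), ts_codes())
  if (length(bad) > 0L)
    stop("unknown label code(s): ", paste(bad, collapse = ", "))
  structure(list(labels = labels, patient_id = as.character(patient_id)),
            class = "ts_image")
}

#' @export
print.ts_image <- function(x, ...) {
  cnt <- count_tiles(x)
  cat(sprintf("ts_image '%s': %d x %d tiles\n", x$patient_id,
              nrow(x$labels), ncol(x$labels)))
  print(unlist(cnt))
  invisible(x)
}

#' @export
dim.ts_image <- function(x) dim(x$labels)

#' Rule-based reference tile classifiers
#'
#' Returns the three binary tile classifiers of the sequential cascade for
#' synthetic slides, whose tile mean color encodes the compartment (see
#' [render_slide()]): the tumor classifier thresholds the green channel
#' (tumor tiles are rendered darker), the necrosis classifier the red-minus-
#' blue excess, and the lymphocyte classifier the blue-minus-red excess.
#' Each returns a probability in `[0, 1]` for the positive class of its task.
#'
#' @return Named list of functions `tumor`, `necrosis`, `lymphocyte`, each
#'   mapping a tile (list with a `pixels` array in `[0, 1]`) to a
#'   probability.
#' @export
reference_classifiers <- function() {
  ch_mean <- function(tile) 255 * c(mean(tile$pixels[, , 1L]),
                                    mean(tile$pixels[, , 2L]),
                                    mean(tile$pixels[, , 3L]))
  list(
    tumor = function(tile) {
      m <- ch_mean(tile); stats::plogis((87.5 - m[2L]) / 6)
    },
    necrosis = function(tile) {
      m <- ch_mean(tile); stats::plogis((m[1L] - m[3L] - 30) / 6)
    },
    lymphocyte = function(tile) {
      m <- ch_mean(tile); stats::plogis((m[3L] - m[1L] - 20) / 6)
    }
  )
}

#' Sequential binary classification cascade
#'
#' Builds a TS-image from retained tiles using three binary classifiers.
#' Per tile: step 1 separates tumor from stroma; step 2 tests tumor-labelled
#' tiles for necrosis (necrotic tiles are terminal and excluded from the
#' lymphocyte search, since necrosis mimics intratumoral lymphocytes);
#' step 3 tests for lymphocytes within tumor (iTIL) and within stroma
#' (sTIL). Grid cells without a retained tile keep the `excluded` code.
#'
#' @param tiles List of tiles (each with `row`, `col`, `pixels`); typically
#'   the retained set from [filter_tiles()]. `row`/`col` are 0-based grid
#'   indices.
#' @param grid_height,grid_width Tile-grid dimensions.
#' @param t_clf,n_clf,l_clf Classifier functions, tile -> probability, for
#'   the tumor, necrosis and lymphocyte tasks.
#' @param thresholds Named list of per-step decision cutoffs in `[0, 1]`;
#'   default 0.5 each.
#' @param patient_id Identifier for the resulting TS-image.
#' @return A [ts_image()].
#' @export
classify_cascade <- function(tiles, grid_height, grid_width,
                             t_clf, n_clf, l_clf,
                             thresholds = list(tumor = 0.5, necrosis = 0.5,
                                               lymphocyte = 0.5),
                             patient_id = "unknown") {
  for (f in list(t_clf, n_clf, l_clf))
    if (!is.function(f)) stop("all three classifiers must be functions")
  th <- utils::modifyList(list(tumor = 0.5, necrosis = 0.5,
                               lymphocyte = 0.5), thresholds)
  if (any(unlist(th) < 0 | unlist(th) > 1))
    stop("decision thresholds must lie in [0, 1]")
  lab <- matrix(0L, grid_height, grid_width)
  for (tile in tiles) {
    r <- tile$row + 1L; cc <- tile$col + 1L
    if (t_clf(tile) >= th$tumor) {
      if (n_clf(tile) >= th$necrosis) {
        code <- 3L
      } else if (l_clf(tile) >= th$lymphocyte) {
        code <- 4L
      } else code <- 1L
    } else {
      code <- if (l_clf(tile) >= th$lymphocyte) 5L else 2L
    }
    lab[r, cc] <- code
  }
  ts_image(lab, patient_id)
}

#' Union of the two lymphocyte compartments
#'
#' @param ts A `ts_image`.
#' @return Logical matrix, `TRUE` where the tile is iTIL or sTIL.
#' @export
tils_union <- function(ts) {
  stopifnot(inherits(ts, "ts_image"))
  ts$labels == 4L | ts$labels == 5L
}

#' Write / read a TS-image as a grayscale PNG with JSON sidecar
#'
#' Label codes are stored bit-exactly as 8-bit gray values; a `.json`
#' sidecar next to the PNG records the patient id and grid shape.
#'
#' @param ts A `ts_image`.
#' @param path Output PNG path.
#' @return `write_ts_image` returns `path` invisibly; `read_ts_image`
#'   returns a `ts_image`.
#' @export
write_ts_image <- function(ts, path) {
  stopifnot(inherits(ts, "ts_image"))
  png::writePNG(ts$labels / 255, path)
  side <- sub("\\.png$", ".json", path)
  jsonlite::write_json(
    list(patient_id = ts$patient_id,
         grid_height = nrow(ts$labels), grid_width = ncol(ts$labels),
         codes = as.list(ts_codes())),
    side, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ts_image
#' @export
read_ts_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  lab <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  bad <- setdiff(unique(as.vector(lab)), ts_codes())
  if (length(bad) > 0L)
    stop("unknown label code(s) in ", path, ": ",
         paste(sort(bad), collapse = ", "))
  pid <- "unknown"
  side <- sub("\\.png$", ".json", path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$patient_id)) pid <- meta$patient_id
  }
  ts_image(lab, pid)
}
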