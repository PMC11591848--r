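#' Construct a Corsi board layout
#'
#' A board is a set of blocks at fixed positions inside a rectangular
#' display window. Coordinates are in centimetres with the origin at the
#' top-left corner, x increasing rightward and y downward. Blocks are
#' treated as squares of side `block_size_cm` centred on their coordinates;
#' the constructor validates that every block lies inside the window and
#' that no two blocks overlap.
#'
#' @param blocks data frame with columns `id` (integers, contiguous from 1),
#'   `x_cm`, `y_cm` (block centre positions).
#' @param window_w_cm,window_h_cm display window size in cm.
#' @param block_size_cm square block side length in cm, used for the
#'   containment and overlap checks.
#' @return An object of class `cbt_board`.
#' @seealso [default_board()]
#' @export
board_layout <- function(blocks, window_w_cm = 20, window_h_cm = 15,
                         block_size_cm = 1.8) {
  blocks <- as.data.frame(blocks)
  req <- c("id", "x_cm", "y_cm")
  if (!all(req %in% names(blocks))) {
    stop("`blocks` must have columns id, x_cm, y_cm")
  }
  n <- nrow(blocks)
  if (n < 2L) stop("a board needs at least 2 blocks")
  ids <- sort(as.integer(blocks$id))
  if (anyDuplicated(ids) || !identical(ids, seq_len(n))) {
    stop("block ids must be unique and contiguous 1..", n)
  }
  half <- block_size_cm / 2
  inside <- blocks$x_cm >= half & blocks$x_cm <= window_w_cm - half &
    blocks$y_cm >= half & blocks$y_cm <= window_h_cm - half
  if (!all(inside)) {
    stop("blocks outside the window: ", paste(blocks$id[!inside], collapse = ", "))
  }
  d <- as.matrix(stats::dist(blocks[, c("x_cm", "y_cm")]))
  diag(d) <- Inf
  if (any(d < block_size_cm)) {
    stop("overlapping blocks (centres closer than one block size)")
  }
  structure(
    list(blocks = blocks[order(blocks$id), req],
         window_w_cm = window_w_cm, window_h_cm = window_h_cm,
         block_size_cm = block_size_cm),
    class = "cbt_board"
  )
}

#' Default 10-block board
#'
#' The standard computerized CBT display: a 20 x 15 cm window with ten
#' equally sized blocks scattered so that no two overlap. The classical
#' test does not standardise block positions, so this layout is a fixed,
#' arbitrary arrangement shipped for reproducibility.
#'
#' @return A `cbt_board` with 10 blocks.
#' @examples
#' b <- default_board()
#' nrow(b$blocks)
#' @export
default_board <- function() {
  board_layout(
    data.frame(
      id   = 1:10,
      x_cm = c(2.5, 6.0, 10.5, 15.5, 4.0, 9.0, 13.5, 2.0, 7.5, 12.5),
      y_cm = c(2.0, 4.5, 1.5, 3.0, 8.0, 6.5, 9.5, 12.0, 11.5, 13.0)
    ),
    window_w_cm = 20, window_h_cm = 15
  )
}

#' @export
print.cbt_board <- function(x, ...) {
  cat(sprintf("Corsi board: %d blocks in a %g x %g cm window\n",
              nrow(x$blocks), x$window_w_cm, x$window_h_cm))
  invisible(x)
}

#' Write / read a board layout as JSON
#'
#' @param board a `cbt_board`.
#' @param path file path.
#' @return `read_board()` returns a `cbt_board`; `write_board()` returns
#'   `path` invisibly.
#' @export
write_board <- function(board, path) {
  stopifnot(inherits(board, "cbt_board"))
  jsonlite::write_json(
    list(window_w_cm = board$window_w_cm, window_h_cm = board$window_h_cm,
         block_size_cm = board$block_size_cm, blocks = board$blocks),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_board
#' @export
read_board <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  board_layout(j$blocks, j$window_w_cm, j$window_h_cm, j$block_size_cm)
}
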