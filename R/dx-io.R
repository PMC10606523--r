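## OpenDX scalar-grid export/import (APBS/DelPhi-compatible layout:
## z varies fastest in the data stream).

#' Write a grid array as an OpenDX scalar file
#'
#' @param values 3D array on the grid (e.g. eps or phi)
#' @param grid a \linkS4class{GridSpec}
#' @param file output path
#' @param comment header comment line
#' @export
writeDx <- function(values, grid, file, comment = "ContinuumPKa grid") {
  d <- grid@dims
  h <- grid@spacing
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste("#", comment),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", grid@origin[1], grid@origin[2],
            grid@origin[3]),
    sprintf("delta %.6e %.6e %.6e", h, 0, 0),
    sprintf("delta %.6e %.6e %.6e", 0, h, 0),
    sprintf("delta %.6e %.6e %.6e", 0, 0, h),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  v <- as.numeric(aperm(values, c(3, 2, 1)))  # z fastest
  pad <- (3 - length(v) %% 3) %% 3
  vv <- c(v, rep(NA_real_, pad))
  m <- matrix(vv, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines("attribute \"dep\" string \"positions\"", con)
  invisible(file)
}

#' Read an OpenDX scalar file
#'
#' @param file DX path
#' @return list(values = 3D array, grid = \linkS4class{GridSpec})
#' @export
readDx <- function(file) {
  lines <- readLines(file, warn = FALSE)
  gp <- grep("gridpositions", lines, value = TRUE)[1]
  d <- as.integer(utils::tail(strsplit(gp, "\\s+")[[1]], 3))
  org <- as.numeric(strsplit(trimws(sub("origin", "",
                                        grep("^origin", lines,
                                             value = TRUE)[1])), "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  h <- as.numeric(strsplit(trimws(sub("delta", "", deltas[1])),
                           "\\s+")[[1]])[1]
  start <- grep("data follows", lines)[1] + 1
  end <- grep("^attribute", lines)
  end <- if (length(end)) end[1] - 1 else length(lines)
  v <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  stopifnot(length(v) == prod(d))
  arr <- aperm(array(v, dim = rev(d)), c(3, 2, 1))
  list(values = arr, grid = gridSpec(origin = org, dims = d, spacing = h))
}
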