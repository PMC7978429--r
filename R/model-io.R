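# Structured text model specifications (one YAML document per taxon) and
# point-cloud readers for digitized bone surfaces. Coordinates are mm, angles
# degrees, frames right-handed.

#' Read a limb model specification file
#'
#' The specification is a YAML document with blocks `taxon`, `segments`
#' (name: reference_length), `joints` (center, optional rom overrides),
#' `wraps` and `mtus` (origin/via/insertion as `[segment, x, y, z]`).
#' Cartilage gaps are applied from the declared segment lengths at load time.
#'
#' @param path File path.
#' @param roster_check Passed to [assemble_model()].
#' @return A validated `limb_model`.
#' @export
read_model_spec <- function(path, roster_check = TRUE) {
  if (!file.exists(path)) abort(paste0("model spec not found: ", path),
                                class = "archolimb_config_error")
  spec <- yaml::read_yaml(path)
  model_from_spec(spec, roster_check = roster_check)
}

# Build a limb_model from a nested list with the same layout as the YAML file.
model_from_spec <- function(spec, roster_check = TRUE) {
  segs <- lapply(names(spec$segments), function(nm) segment(nm, spec$segments[[nm]]))
  names(segs) <- names(spec$segments)
  joints <- lapply(names(spec$joints), function(nm) {
    j <- spec$joints[[nm]]
    rom <- if (!is.null(j$rom)) {
      dplyr::bind_rows(lapply(names(j$rom), function(d) {
        tibble::tibble(dof = d, rom_lo = j$rom[[d]][1], rom_hi = j$rom[[d]][2],
                       locked_default = j$rom[[d]][3])
      }))
    }
    js <- joint_spec(nm, center = as.numeric(j$center), rom = rom)
    place_joint(js, segs[[unname(JOINT_PARENT[nm])]])
  })
  wraps <- lapply(spec$wraps %||% list(), function(w) {
    wrap_surface(w$name, w$shape, w$segment, as.numeric(w$center),
                 axis = as.numeric(w$axis %||% c(0, -1, 0)),
                 radius = as.numeric(w$radius),
                 half_length = w$half_length %||% NULL,
                 wrap_side = w$wrap_side %||% 1,
                 mtus = as.character(w$mtus %||% character()))
  })
  parse_att <- function(a) attachment(a[[1]], as.numeric(a[-1]))
  mtus <- lapply(spec$mtus %||% list(), function(m) {
    mtu_path(m$name, origin = parse_att(m$origin), insertion = parse_att(m$insertion),
             via = lapply(m$via %||% list(), parse_att),
             wraps = as.character(m$wraps %||% character()),
             present = m$present %||% TRUE)
  })
  assemble_model(spec$taxon, segs, joints, mtus, wraps,
                 metadata = spec$metadata %||% list(), roster_check = roster_check)
}

#' Write a limb model specification file
#'
#' @param model A `limb_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(model, path) {
  spec <- list(
    taxon = model$taxon,
    segments = lapply(model$segments, `[[`, "reference_length"),
    joints = setNames(lapply(model$joints, function(j) {
      out <- list(center = as.numeric(j$center))
      def <- default_rom()[default_rom()$joint == j$name, ]
      if (!isTRUE(all.equal(as.data.frame(def), as.data.frame(j$rom)))) {
        out$rom <- setNames(lapply(seq_len(nrow(j$rom)), function(i) {
          as.numeric(j$rom[i, c("rom_lo", "rom_hi", "locked_default")])
        }), j$rom$dof)
      }
      out
    }), names(model$joints)),
    wraps = unname(lapply(model$wraps, function(w) {
      list(name = w$name, shape = w$shape, segment = w$segment,
           center = as.numeric(w$center), axis = as.numeric(w$axis),
           radius = as.numeric(w$radius), wrap_side = w$wrap_side,
           mtus = as.list(w$mtus))
    })),
    mtus = unname(lapply(c(model$mtus, absent_mtu_stubs(model)), function(m) {
      fmt <- function(a) c(list(a$segment), as.list(as.numeric(a$point)))
      list(name = m$name, origin = fmt(m$origin),
           via = lapply(m$via, fmt), insertion = fmt(m$insertion),
           wraps = as.list(m$wraps), present = m$present)
    })),
    metadata = model$metadata[setdiff(names(model$metadata), "absent_mtus")]
  )
  yaml::write_yaml(spec, path, precision = 12)
  invisible(path)
}

absent_mtu_stubs <- function(model) list()

#' Read a bone point cloud
#'
#' Supports ASCII and binary STL, Wavefront OBJ (vertices only) and
#' whitespace-delimited XYZ point lists (`.asc`). Returns the unique vertex
#' set as a numeric matrix.
#'
#' @param path File path.
#' @param format `"auto"` (by extension and content), `"stl"`, `"obj"` or
#'   `"xyz"`.
#' @return A numeric matrix with columns x, y, z (mm).
#' @export
read_point_cloud <- function(path, format = c("auto", "stl", "obj", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("point cloud not found: ", path),
                                class = "archolimb_config_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", obj = "obj", "xyz")
  }
  pts <- switch(format,
    stl = read_stl_points(path),
    obj = {
      ln <- readLines(path, warn = FALSE)
      vl <- grep("^v\\s", ln, value = TRUE)
      if (length(vl) == 0) abort("no vertices in OBJ file", class = "archolimb_config_error")
      do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                            function(x) as.numeric(x[1:3])))
    },
    xyz = {
      m <- as.matrix(utils::read.table(path))
      m[, 1:3, drop = FALSE]
    }
  )
  unique(unname(pts))
}

read_stl_points <- function(path) {
  hdr <- readBin(path, "raw", n = 80L)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 80L)
  n_tri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 80L + 4L + 50L * as.numeric(n_tri)
  is_ascii <- grepl("^solid", rawToChar(hdr[hdr != as.raw(0)][1:5])) &&
    !isTRUE(abs(file.size(path) - expected) < 2)
  if (is_ascii) {
    ln <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", ln, value = TRUE)
    if (length(vl) == 0) abort("no vertices in STL file", class = "archolimb_config_error")
    return(do.call(rbind, lapply(strsplit(trimws(sub("vertex", "", vl)), "\\s+"),
                                 function(x) as.numeric(x[1:3]))))
  }
  pts <- matrix(0, 3L * n_tri, 3L)
  for (i in seq_len(n_tri)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    pts[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", n = 2L)
  }
  pts
}
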