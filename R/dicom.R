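# Minimal DICOM reader: enough of the Part-10 explicit-VR little-endian
# encoding to pull an arc beam's control point sequence out of an RT Plan.
# Scope is deliberate -- the CSV plan dialect is the normative input; DICOM
# import is a convenience for plans exported by a TPS. Unsupported encodings
# raise classed errors instead of guessing.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_u16 <- function(b, i) as.integer(b[i]) + 256L * as.integer(b[i + 1L])
dcm_u32 <- function(b, i) sum(as.numeric(b[i:(i + 3L)]) * 256^(0:3))

DCM_LONG_VRS <- c("OB", "OW", "OF", "OL", "OD", "SQ", "UC", "UR", "UT", "UN")

# Parse one explicit-VR data element at `pos`. Returns the tag ("GGGGEEEE"),
# its value (raw vector, or a list of datasets for SQ, or NULL for a
# delimiter), the next position, and whether the element was an item /
# sequence delimiter.
dcm_parse_element <- function(b, pos) {
  group <- dcm_u16(b, pos); elem <- dcm_u16(b, pos + 2L)
  tag <- sprintf("%04X%04X", group, elem)
  if (group == 0xFFFE) {  # item or delimitation: no VR, 4-byte length
    return(list(tag = tag, value = NULL, pos = pos + 8L,
                delim = elem %in% c(0xE00D, 0xE0DD)))
  }
  vr <- rawToChar(b[(pos + 4L):(pos + 5L)])
  if (vr %in% DCM_LONG_VRS) {
    len <- dcm_u32(b, pos + 8L)
    pos <- pos + 12L
  } else {
    len <- dcm_u16(b, pos + 6L)
    pos <- pos + 8L
  }
  if (vr == "SQ" || (vr == "UN" && len == 4294967295)) {
    sq <- dcm_parse_sequence(b, pos, len)
    return(list(tag = tag, value = sq$items, pos = sq$pos, delim = FALSE))
  }
  if (len == 4294967295)
    arcv_stop("undefined-length element outside a sequence",
              "arcv_unsupported_content")
  value <- if (len > 0) b[pos:(pos + len - 1L)] else raw(0)
  list(tag = tag, value = value, pos = pos + len, delim = FALSE)
}

# Parse a stream of data elements in [pos, end]; returns a dataset: a named
# list keyed "GGGGEEEE" holding raw values, or lists of datasets for SQ.
# Stops early (consuming the delimiter) at an item delimitation tag, which
# ends an undefined-length item's dataset.
dcm_parse <- function(b, pos, end) {
  ds <- list()
  while (pos + 7L <= end + 1L) {
    el <- dcm_parse_element(b, pos)
    pos <- el$pos
    if (isTRUE(el$delim)) break
    ds[[el$tag]] <- el$value
  }
  list(ds = ds, pos = pos)
}

dcm_parse_sequence <- function(b, pos, len) {
  undef <- len == 4294967295
  end <- if (undef) length(b) else pos + len - 1L
  items <- list()
  while (pos + 7L <= end + 1L) {
    group <- dcm_u16(b, pos); elem <- dcm_u16(b, pos + 2L)
    ilen <- dcm_u32(b, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && elem == 0xE0DD) break           # sequence delim
    if (!(group == 0xFFFE && elem == 0xE000))
      arcv_stop("malformed sequence: expected an item tag",
                "arcv_unsupported_content")
    if (ilen == 4294967295) {
      parsed <- dcm_parse(b, pos, end)                     # ends at E00D
    } else {
      parsed <- dcm_parse(b, pos, pos + ilen - 1L)
      parsed$pos <- pos + ilen
    }
    items[[length(items) + 1L]] <- parsed$ds
    pos <- parsed$pos
    if (!undef && pos > end) break
  }
  list(items = items, pos = pos)
}

dcm_string <- function(ds, tag) {
  v <- ds[[tag]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v))
}

dcm_numbers <- function(ds, tag) {
  s <- dcm_string(ds, tag)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\", fixed = TRUE)[[1L]])
}

dcm_read <- function(path) {
  if (!file.exists(path))
    arcv_stop(sprintf("file not found: %s", path), "arcv_io_error")
  b <- readBin(path, "raw", file.size(path))
  if (length(b) < 140L || rawToChar(b[129:132]) != "DICM")
    arcv_stop(sprintf("%s is not a DICOM Part-10 file", path),
              "arcv_unsupported_content")
  # file meta group (0002,xxxx) is always explicit little endian
  pos <- 133L
  meta <- list()
  while (pos + 7L <= length(b) && dcm_u16(b, pos) == 0x0002) {
    el <- dcm_parse_element(b, pos)
    meta[[el$tag]] <- el$value
    pos <- el$pos
  }
  ts <- dcm_string(meta, "00020010") %||% TS_EXPLICIT_LE
  if (ts != TS_EXPLICIT_LE)
    arcv_stop(sprintf("unsupported transfer syntax %s (only explicit VR little endian)",
                      ts), "arcv_unsupported_content")
  dcm_parse(b, pos, length(b))$ds
}

#' Read an arc plan from a DICOM RT Plan file
#'
#' Extracts the first dynamic MLC beam's control point sequence and maps it
#' onto the [arc_plan()] convention: cumulative meterset weights are rescaled
#' to cumulative MU using the beam meterset referenced from the fraction
#' group sequence, MLC bank 1/2 map to banks A/B, and X/Y (or ASYMX/ASYMY)
#' device positions to the four jaws. Gantry angle, jaw and MLC positions
#' omitted from later control points carry forward from the previous control
#' point, per DICOM semantics.
#'
#' Only uncompressed explicit-VR little-endian files are supported; anything
#' else, a missing control point sequence, a static (single control point)
#' beam, or a beam without an MLC raises an unsupported-content error.
#'
#' @param path Path to a DICOM RT Plan.
#' @param geometry A [machine_geometry()].
#' @return A validated [arc_plan()].
#' @export
read_dicom_plan <- function(path, geometry = machine_geometry()) {
  ds <- dcm_read(path)
  beams <- ds[["300A00B0"]]
  if (is.null(beams) || length(beams) == 0L)
    arcv_stop("RT Plan has no beam sequence", "arcv_unsupported_content")

  # beam number -> meterset from the fraction group sequence
  metersets <- list()
  for (fg in ds[["300A0070"]] %||% list()) {
    for (rb in fg[["300C0004"]] %||% list()) {
      num <- dcm_numbers(rb, "300C0006")
      ms <- dcm_numbers(rb, "300A0086")
      if (!is.null(num) && !is.null(ms))
        metersets[[as.character(num)]] <- ms
    }
  }

  np <- geometry$n_leaf_pairs
  for (beam in beams) {
    cps <- beam[["300A0111"]]
    if (is.null(cps))
      arcv_stop("beam has no control point sequence",
                "arcv_unsupported_content")
    if (length(cps) < 2L)
      arcv_stop("static (single control point) beam is not an arc",
                "arcv_unsupported_content")

    n <- length(cps)
    weights <- numeric(n); gantry <- numeric(n)
    bank_a <- matrix(NA_real_, n, np); bank_b <- matrix(NA_real_, n, np)
    jaws <- matrix(NA_real_, n, 4L)
    sense <- NULL
    has_mlc <- FALSE
    for (i in seq_len(n)) {
      cp <- cps[[i]]
      w <- dcm_numbers(cp, "300A0134")
      if (is.null(w))
        arcv_stop("control point lacks a cumulative meterset weight",
                  "arcv_unsupported_content")
      weights[i] <- w
      g <- dcm_numbers(cp, "300A011E")
      if (is.null(g) && i == 1L)
        arcv_stop("first control point lacks a gantry angle",
                  "arcv_unsupported_content")
      gantry[i] <- if (!is.null(g)) wrap360(g) else gantry[i - 1L]
      rd <- dcm_string(cp, "300A011F")
      if (is.null(sense) && !is.null(rd) && rd %in% c("CW", "CC"))
        sense <- if (rd == "CW") 1L else -1L
      if (i > 1L) {  # carry forward
        bank_a[i, ] <- bank_a[i - 1L, ]; bank_b[i, ] <- bank_b[i - 1L, ]
        jaws[i, ] <- jaws[i - 1L, ]
      }
      for (dev in cp[["300A011A"]] %||% list()) {
        type <- dcm_string(dev, "300A00B8")
        pos <- dcm_numbers(dev, "300A011C")
        if (is.null(type) || is.null(pos)) next
        if (type == "MLCX") {
          if (length(pos) != 2L * np)
            arcv_stop(sprintf("MLCX carries %d positions, expected %d",
                              length(pos), 2L * np), "arcv_format_error")
          bank_a[i, ] <- pos[seq_len(np)]
          bank_b[i, ] <- pos[np + seq_len(np)]
          has_mlc <- TRUE
        } else if (type %in% c("X", "ASYMX")) {
          jaws[i, 1:2] <- sort(pos[1:2])
        } else if (type %in% c("Y", "ASYMY")) {
          jaws[i, 3:4] <- sort(pos[1:2])
        }
      }
    }
    if (!has_mlc)
      arcv_stop("beam has no MLCX device: not an MLC-shaped arc",
                "arcv_unsupported_content")
    if (anyNA(bank_a) || anyNA(bank_b))
      arcv_stop("first control point lacks MLC positions",
                "arcv_unsupported_content")
    # jaws omitted entirely: treat as parked wide open
    jaws[is.na(jaws)] <- rep(c(-200, 200, -200, 200),
                             each = n)[is.na(jaws)]

    final_w <- dcm_numbers(beam, "300A010E") %||% weights[n]
    beam_num <- dcm_numbers(beam, "300A00C0")
    meterset <- metersets[[as.character(beam_num %||% "")]] %||% NULL
    mu <- if (!is.null(meterset) && final_w > 0)
      weights / final_w * meterset else weights

    return(arc_plan(
      patient_id = dcm_string(ds, "00100020") %||% "unknown",
      field_id = dcm_string(beam, "300A00C2") %||%
        sprintf("BEAM%s", beam_num %||% "1"),
      collimator_deg = (dcm_numbers(cps[[1L]], "300A0120") %||% 45) %% 360,
      rotation_sense = sense,
      cumulative_mu = mu, gantry_deg = gantry,
      bank_a = bank_a, bank_b = bank_b, jaws = jaws,
      geometry = geometry
    ))
  }
  arcv_stop("no usable arc beam found", "arcv_unsupported_content")
}
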