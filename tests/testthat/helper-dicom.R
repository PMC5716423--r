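# Writes a minimal synthetic DICOM RT Plan (explicit VR little endian,
# defined lengths) for fixture round-trips. Independent of the package's
# parser: bytes are assembled directly from the Part-10 encoding rules.

dcm_w16 <- function(x) as.raw(c(x %% 256, x %/% 256))
dcm_w32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                (x %/% 65536) %% 256,
                                (x %/% 16777216) %% 256))

dcm_pad <- function(value, pad = as.raw(0x20)) {
  if (length(value) %% 2 == 1) c(value, pad) else value
}

# One data element. Short-form VRs carry a 2-byte length; SQ uses the
# 4-byte form with reserved bytes.
dcm_el <- function(group, elem, vr, value) {
  value <- dcm_pad(value, if (vr == "UI") as.raw(0) else as.raw(0x20))
  head <- c(dcm_w16(group), dcm_w16(elem), charToRaw(vr))
  if (vr == "SQ") c(head, as.raw(c(0, 0)), dcm_w32(length(value)), value)
  else c(head, dcm_w16(length(value)), value)
}

dcm_txt <- function(group, elem, vr, s) dcm_el(group, elem, vr, charToRaw(s))
dcm_ds <- function(group, elem, vals)
  dcm_txt(group, elem, "DS", paste(sprintf("%.10g", vals), collapse = "\\"))

dcm_item <- function(content) c(dcm_w16(0xFFFE), dcm_w16(0xE000),
                                dcm_w32(length(content)), content)
dcm_sq <- function(group, elem, items)
  dcm_el(group, elem, "SQ", unlist(lapply(items, dcm_item)))

# Assemble an RT Plan: one beam, one fraction group referencing it.
write_synthetic_rtplan <- function(path, patient_id = "PTDCM",
                                   beam_name = "ARC1",
                                   weights = c(0, 0.5, 1),
                                   gantry = c(175, 171, 167),
                                   meterset = 200,
                                   bank_a = NULL, bank_b = NULL,
                                   jaws = c(-50, 50, -80, 80),
                                   rotation = "CC",
                                   include_mlc = TRUE) {
  n <- length(weights)
  if (is.null(bank_a)) bank_a <- matrix(-10, n, 40)
  if (is.null(bank_b)) bank_b <- matrix(10, n, 40)

  cps <- lapply(seq_len(n), function(i) {
    devs <- list(
      dcm_item(c(dcm_txt(0x300A, 0x00B8, "CS", "ASYMX"),
                 dcm_ds(0x300A, 0x011C, jaws[1:2]))),
      dcm_item(c(dcm_txt(0x300A, 0x00B8, "CS", "ASYMY"),
                 dcm_ds(0x300A, 0x011C, jaws[3:4])))
    )
    if (include_mlc)
      devs <- c(devs, list(dcm_item(c(
        dcm_txt(0x300A, 0x00B8, "CS", "MLCX"),
        dcm_ds(0x300A, 0x011C, c(bank_a[i, ], bank_b[i, ]))))))
    content <- c(
      dcm_txt(0x300A, 0x0112, "IS", sprintf("%d", i - 1L)),
      dcm_ds(0x300A, 0x011E, gantry[i]),
      dcm_txt(0x300A, 0x011F, "CS", rotation),
      if (i == 1L) dcm_ds(0x300A, 0x0120, 45),
      dcm_el(0x300A, 0x011A, "SQ", unlist(devs)),
      dcm_ds(0x300A, 0x0134, weights[i])
    )
    content
  })

  beam <- c(
    dcm_txt(0x300A, 0x00C0, "IS", "1"),
    dcm_txt(0x300A, 0x00C2, "LO", beam_name),
    dcm_ds(0x300A, 0x010E, weights[n]),
    dcm_sq(0x300A, 0x0111, cps)
  )
  fg <- dcm_item(c(
    dcm_txt(0x300A, 0x0071, "IS", "1"),
    dcm_sq(0x300C, 0x0004, list(c(
      dcm_ds(0x300A, 0x0086, meterset),
      dcm_txt(0x300C, 0x0006, "IS", "1")
    )))
  ))

  dataset <- c(
    dcm_txt(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_txt(0x0010, 0x0020, "LO", patient_id),
    dcm_el(0x300A, 0x0070, "SQ", fg),
    dcm_sq(0x300A, 0x00B0, list(beam))
  )

  meta <- dcm_txt(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  bytes <- c(rep(as.raw(0), 128), charToRaw("DICM"), meta, dataset)
  writeBin(bytes, path)
  invisible(path)
}
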