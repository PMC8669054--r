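# Minimal DICOM Part 10 support: enough of the Explicit VR Little Endian
# encoding to write small CT instances with controlled defects and to read
# them back for triage. Not a general DICOM implementation.

UID_CT_IMAGE_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_IMPL_CLASS <- "1.2.826.0.1.3680043.10.1101.1"
UID_ROOT <- "1.2.826.0.1.3680043.10.1101"

# VRs using the 4-byte length form in Explicit VR
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.dcm_string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                     "PN", "SH", "ST", "TM", "UI")
.dcm_known_vrs <- c(.dcm_long_vrs, .dcm_string_vrs, "UL", "US", "SL", "SS",
                    "AT", "FL", "FD")

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                             endian = "little")
.u32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- x %/% 65536
  c(.u16(lo), .u16(hi))
}

.dcm_string_value <- function(value, vr) {
  v <- charToRaw(paste(value, collapse = "\\"))
  if (length(v) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    v <- c(v, pad)
  }
  v
}

# Encode one data element in Explicit VR Little Endian. `declared_length`
# lets a caller lie about the value length (used to forge truncated files).
dcm_element <- function(group, element, vr, value,
                        declared_length = NULL) {
  bytes <- if (vr %in% .dcm_string_vrs) .dcm_string_value(value, vr)
  else if (vr == "US") do.call(c, lapply(value, .u16))
  else if (vr == "UL") do.call(c, lapply(value, .u32))
  else if (is.raw(value)) value
  else stop_validation(sprintf("unsupported VR for writing: %s", vr),
                       "cohortforge_dicom_write_error")
  len <- declared_length %||% length(bytes)
  head_bytes <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    c(head_bytes, as.raw(c(0L, 0L)), .u32(len), bytes)
  } else {
    c(head_bytes, .u16(len), bytes)
  }
}

dcm_uid <- function(...) {
  suffix <- paste(..., sep = ".")
  paste(UID_ROOT, suffix, sep = ".")
}

# Numeric UID component derived from an arbitrary accession string
.acc_uid_component <- function(acc) {
  codes <- utf8ToInt(acc)
  comp <- paste(codes %% 100, collapse = "")
  substr(paste0("1", comp), 1L, 24L)  # leading 1: no zero-led component
}

.gradient_pixels <- function(rows, cols, offset = 0L) {
  vals <- (seq_len(rows * cols) - 1L + offset) %% 4096L
  writeBin(as.integer(vals), raw(), size = 2L, endian = "little")
}

#' Write one synthetic CT DICOM instance
#'
#' Produces a Part 10 file (128-byte preamble, `DICM` magic, file meta
#' group, Explicit VR Little Endian dataset) containing a small synthetic
#' gradient image plus the patient/study metadata triage relies on.
#' Defect switches forge the content-level failures seen in real
#' archives: `truncate_pixel` declares the full pixel length but writes
#' only half the payload (metadata parses, pixels do not), and `bad_vr`
#' writes an invalid value representation so the dataset is undecodable.
#'
#' @param path output file path.
#' @param patient_id canonical MRN stored in PatientID.
#' @param patient_name PatientName value.
#' @param accession AccessionNumber value.
#' @param study_date ISO-8601 date (written as DICOM `DA`).
#' @param instance_number integer instance number.
#' @param image_type ImageType components, e.g.
#'   `c("ORIGINAL", "PRIMARY", "AXIAL")` or
#'   `c("ORIGINAL", "PRIMARY", "LOCALIZER")`.
#' @param rows,cols image dimensions (16-bit monochrome).
#' @param truncate_pixel forge a truncated pixel payload.
#' @param bad_vr forge an undecodable element.
#' @return `path`, invisibly.
#' @export
dicom_write_instance <- function(path, patient_id, patient_name, accession,
                                 study_date, instance_number = 1L,
                                 image_type = c("ORIGINAL", "PRIMARY",
                                                "AXIAL"),
                                 rows = 8L, cols = 8L,
                                 truncate_pixel = FALSE, bad_vr = FALSE) {
  da <- gsub("-", "", as.character(study_date))
  acc_comp <- .acc_uid_component(accession)
  sop_uid <- dcm_uid(acc_comp, 1, instance_number)
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_element(0x0002, 0x0002, "UI", UID_CT_IMAGE_STORAGE),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE),
    dcm_element(0x0002, 0x0012, "UI", UID_IMPL_CLASS)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body)

  px <- .gradient_pixels(rows, cols, offset = instance_number)
  px_declared <- length(px)
  if (truncate_pixel) px <- px[seq_len(length(px) %/% 2L)]

  dataset <- c(
    dcm_element(0x0008, 0x0008, "CS", image_type),
    dcm_element(0x0008, 0x0016, "UI", UID_CT_IMAGE_STORAGE),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0020, "DA", da),
    dcm_element(0x0008, 0x0050, "SH", accession),
    if (bad_vr) {
      # invalid VR bytes: any conformant reader must reject the dataset
      c(.u16(0x0008), .u16(0x0060), charToRaw("ZZ"), .u16(2L),
        charToRaw("CT"))
    } else {
      dcm_element(0x0008, 0x0060, "CS", "CT")
    },
    dcm_element(0x0010, 0x0010, "PN", patient_name),
    dcm_element(0x0010, 0x0020, "LO", patient_id),
    dcm_element(0x0020, 0x000D, "UI", dcm_uid(acc_comp)),
    dcm_element(0x0020, 0x000E, "UI", dcm_uid(acc_comp, 1)),
    dcm_element(0x0020, 0x0013, "IS", as.character(instance_number)),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", rows),
    dcm_element(0x0028, 0x0011, "US", cols),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x7FE0, 0x0010, "OW", px, declared_length = px_declared)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

.dcm_stop <- function(msg) {
  stop(errorCondition(msg, class = c("cohortforge_dicom_encoding_error",
                                     "cohortforge_validation_error")))
}

.read_u16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}
.read_u32 <- function(bytes, pos) {
  .read_u16(bytes, pos) + 65536 * .read_u16(bytes, pos + 2L)
}

#' Read one DICOM instance written in Explicit VR Little Endian
#'
#' Parses the Part 10 preamble, file meta group and dataset. Raises a
#' condition of class `cohortforge_dicom_encoding_error` when the file is
#' not decodable (missing magic, unknown VR, unsupported transfer syntax,
#' or a header truncated mid-element). A truncated *pixel* payload is not
#' an encoding error: the metadata is returned with `pixel_ok = FALSE`,
#' mirroring how archives surface corrupt studies whose headers still
#' parse.
#'
#' @param path file to read.
#' @return A list: `elements` (named by `"GGGG,EEEE"`), `transfer_syntax`,
#'   `patient_id`, `patient_name`, `accession`, `modality`, `study_date`,
#'   `image_type` (character vector of components), `instance_number`,
#'   `is_localizer`, `pixel_ok`, `pixel_bytes_declared`,
#'   `pixel_bytes_present`.
#' @export
dicom_read_instance <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 132L ||
      rawToChar(bytes[129:132]) != "DICM") {
    .dcm_stop("not a DICOM Part 10 file (missing DICM magic)")
  }
  pos <- 133L
  n <- length(bytes)
  elements <- list()
  pixel_ok <- NA
  px_declared <- NA_integer_
  px_present <- NA_integer_
  while (pos + 7L <= n) {
    group <- .read_u16(bytes, pos)
    element <- .read_u16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!vr %in% .dcm_known_vrs) {
      .dcm_stop(sprintf("invalid VR '%s' at offset %d", vr, pos - 1L))
    }
    if (vr %in% .dcm_long_vrs) {
      if (pos + 11L > n) .dcm_stop("truncated element header")
      len <- .read_u32(bytes, pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- .read_u16(bytes, pos + 6L)
      vstart <- pos + 8L
    }
    tag <- sprintf("%04X,%04X", group, element)
    if (group == 0x7FE0 && element == 0x0010) {
      px_declared <- len
      px_present <- max(0L, n - vstart + 1L)
      pixel_ok <- px_present >= len
      break
    }
    if (vstart + len - 1L > n) {
      .dcm_stop(sprintf("element %s overruns the file", tag))
    }
    val_raw <- if (len > 0L) bytes[vstart:(vstart + len - 1L)] else raw(0)
    value <- if (vr %in% .dcm_string_vrs) {
      v <- rawToChar(val_raw[val_raw != as.raw(0L)])
      strsplit(trimws(v, which = "right"), "\\", fixed = TRUE)[[1]]
    } else if (vr == "US") {
      vapply(seq_len(len %/% 2L),
             function(i) .read_u16(val_raw, 2L * i - 1L), integer(1))
    } else if (vr == "UL") {
      vapply(seq_len(len %/% 4L),
             function(i) .read_u32(val_raw, 4L * i - 3L), numeric(1))
    } else val_raw
    elements[[tag]] <- value
    pos <- vstart + len
  }
  ts <- elements[["0002,0010"]] %||% NA_character_
  if (!is.na(ts[1]) && ts[1] != UID_EXPLICIT_VR_LE) {
    .dcm_stop(sprintf("unsupported transfer syntax %s", ts[1]))
  }
  img_type <- elements[["0008,0008"]] %||% character(0)
  list(elements = elements,
       transfer_syntax = ts[1],
       patient_id = (elements[["0010,0020"]] %||% NA_character_)[1],
       patient_name = (elements[["0010,0010"]] %||% NA_character_)[1],
       accession = (elements[["0008,0050"]] %||% NA_character_)[1],
       modality = (elements[["0008,0060"]] %||% NA_character_)[1],
       study_date = (elements[["0008,0020"]] %||% NA_character_)[1],
       image_type = img_type,
       instance_number =
         suppressWarnings(as.integer((elements[["0020,0013"]] %||%
                                        NA_character_)[1])),
       is_localizer = any(toupper(img_type) == "LOCALIZER"),
       pixel_ok = isTRUE(pixel_ok),
       pixel_bytes_declared = px_declared,
       pixel_bytes_present = px_present)
}

#' Summarize every instance in a study directory
#'
#' Reads each `.dcm` file in the directory, tolerating undecodable
#' instances, and reports the per-study facts triage needs.
#'
#' @param dir study directory containing `.dcm` files.
#' @return A list: `n_files`, `n_decoded`, `any_encoding_error`,
#'   `any_pixel_failure`, `all_localizer` (of decoded instances),
#'   `patient_names`, `instances` (per-file data.frame).
#' @export
dicom_read_study <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  rows <- lapply(files, function(f) {
    inst <- tryCatch(dicom_read_instance(f),
                     cohortforge_dicom_encoding_error = function(e) NULL)
    if (is.null(inst)) {
      data.frame(file = basename(f), decoded = FALSE, pixel_ok = FALSE,
                 is_localizer = NA, patient_name = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(file = basename(f), decoded = TRUE,
                 pixel_ok = inst$pixel_ok,
                 is_localizer = inst$is_localizer,
                 patient_name = inst$patient_name,
                 stringsAsFactors = FALSE)
    }
  })
  instances <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0), decoded = logical(0),
               pixel_ok = logical(0), is_localizer = logical(0),
               patient_name = character(0), stringsAsFactors = FALSE)
  decoded <- instances[instances$decoded, , drop = FALSE]
  list(n_files = nrow(instances),
       n_decoded = nrow(decoded),
       any_encoding_error = any(!instances$decoded),
       any_pixel_failure = nrow(decoded) > 0 && any(!decoded$pixel_ok),
       all_localizer = nrow(decoded) > 0 && all(decoded$is_localizer),
       patient_names = unique(decoded$patient_name),
       instances = instances)
}

#' Render a study directory with an injected failure mode
#'
#' Writes `n_instances` DICOM files for one study under
#' `out_dir/<accession>/`, shaped by the injected mode: `none` renders
#' clean axial instances; `topogram_only` renders only localizer
#' instances; `corrupted` truncates the pixel payload of the first
#' instance; `encoding_error` makes the first instance undecodable;
#' `test_patient` renders clean instances (the sentinel patient name is
#' whatever `patient_name` carries).
#'
#' @param out_dir root directory for rendered studies.
#' @param accession study accession (directory name).
#' @param mode one of `none`, `topogram_only`, `corrupted`,
#'   `encoding_error`, `test_patient`.
#' @param patient_id canonical MRN.
#' @param patient_name patient name to embed.
#' @param study_date ISO-8601 study date.
#' @param n_instances number of instances to write.
#' @return The study directory path, invisibly.
#' @export
render_dicom_study <- function(out_dir, accession, mode, patient_id,
                               patient_name, study_date,
                               n_instances = 4L) {
  modes <- c("none", "topogram_only", "corrupted", "encoding_error",
             "test_patient")
  if (!mode %in% modes) {
    stop_validation(sprintf("unknown DICOM render mode '%s'", mode),
                    "cohortforge_bad_render_mode")
  }
  sdir <- file.path(out_dir, accession)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_instances)) {
    dicom_write_instance(
      file.path(sdir, sprintf("inst_%03d.dcm", i)),
      patient_id = patient_id,
      patient_name = patient_name,
      accession = accession,
      study_date = study_date,
      instance_number = i,
      image_type = if (mode == "topogram_only")
        c("ORIGINAL", "PRIMARY", "LOCALIZER")
      else c("ORIGINAL", "PRIMARY", "AXIAL"),
      truncate_pixel = (mode == "corrupted" && i == 1L),
      bad_vr = (mode == "encoding_error" && i == 1L)
    )
  }
  invisible(sdir)
}

#' Render every study in a fixture manifest
#'
#' @param manifest data.frame with columns `accession`, `mode`,
#'   `patient_id` (canonical MRN), `patient_name`, `study_date`,
#'   `n_instances`.
#' @param out_dir root directory; one subdirectory per accession.
#' @return `out_dir`, invisibly.
#' @export
render_dicom_fixtures <- function(manifest, out_dir) {
  assert_columns(manifest, c("accession", "mode", "patient_id",
                             "patient_name", "study_date", "n_instances"),
                 "DICOM manifest")
  for (i in seq_len(nrow(manifest))) {
    render_dicom_study(out_dir,
                       accession = manifest$accession[i],
                       mode = manifest$mode[i],
                       patient_id = manifest$patient_id[i],
                       patient_name = manifest$patient_name[i],
                       study_date = manifest$study_date[i],
                       n_instances = manifest$n_instances[i])
  }
  invisible(out_dir)
}
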