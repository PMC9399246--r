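# write tiny synthetic CT DICOM series at test time via the pre-installed
# Python pydicom (the same interpreter the package's reader bridges to)

dicom_writer_py <- c(
  "import os, sys",
  "import numpy as np",
  "import pydicom",
  "from pydicom.dataset import Dataset, FileMetaDataset",
  "from pydicom.uid import ExplicitVRLittleEndian, generate_uid",
  "",
  "def make_series(outdir, n_slices=2, rows=8, cols=8, spacing=(1.0, 1.0),",
  "                dz=2.0, intercept=-1024.0, slope=1.0, value=1024,",
  "                reverse_names=False, last_slice_spacing=None):",
  "    os.makedirs(outdir, exist_ok=True)",
  "    series_uid = generate_uid()",
  "    for i in range(n_slices):",
  "        ds = Dataset()",
  "        meta = FileMetaDataset()",
  "        meta.MediaStorageSOPClassUID = '1.2.840.10008.5.1.4.1.1.2'",
  "        meta.MediaStorageSOPInstanceUID = generate_uid()",
  "        meta.TransferSyntaxUID = ExplicitVRLittleEndian",
  "        ds.file_meta = meta",
  "        ds.SOPClassUID = meta.MediaStorageSOPClassUID",
  "        ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID",
  "        ds.SeriesInstanceUID = series_uid",
  "        ds.Modality = 'CT'",
  "        ds.Rows = rows",
  "        ds.Columns = cols",
  "        sp = spacing",
  "        if last_slice_spacing and i == n_slices - 1:",
  "            sp = last_slice_spacing",
  "        ds.PixelSpacing = [str(sp[0]), str(sp[1])]",
  "        ds.SliceThickness = str(dz)",
  "        ds.ImagePositionPatient = ['0', '0', str(i * dz)]",
  "        ds.RescaleIntercept = str(intercept)",
  "        ds.RescaleSlope = str(slope)",
  "        ds.BitsAllocated = 16",
  "        ds.BitsStored = 16",
  "        ds.HighBit = 15",
  "        ds.PixelRepresentation = 0",
  "        ds.SamplesPerPixel = 1",
  "        ds.PhotometricInterpretation = 'MONOCHROME2'",
  "        arr = np.full((rows, cols), value, dtype=np.uint16)",
  "        arr[0, :] = value + i",
  "        ds.PixelData = arr.tobytes()",
  "        name = 'slice_%c.dcm' % chr(122 - i) if reverse_names \\",
  "            else 'slice_%02d.dcm' % i",
  "        pydicom.dcmwrite(os.path.join(outdir, name), ds,",
  "                         enforce_file_format=True)",
  "",
  "if __name__ == '__main__':",
  "    kind = sys.argv[1]",
  "    outdir = sys.argv[2]",
  "    if kind == 'basic':",
  "        make_series(outdir)",
  "    elif kind == 'reversed':",
  "        make_series(outdir, reverse_names=True)",
  "    elif kind == 'mixed_spacing':",
  "        make_series(outdir, last_slice_spacing=(2.0, 2.0))",
  "    else:",
  "        raise SystemExit('unknown kind ' + kind)"
)

write_test_dicom <- function(kind, outdir) {
  py <- file.path(tempdir(), "write_test_dicom.py")
  if (!file.exists(py)) writeLines(dicom_writer_py, py)
  status <- system2("python", c(shQuote(py), kind, shQuote(outdir)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0) {
    stop("test DICOM writer failed: ", paste(status, collapse = "\n"))
  }
  outdir
}
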