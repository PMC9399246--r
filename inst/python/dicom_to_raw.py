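"""Read one axial CT DICOM series and dump it as raw float32 + JSON header.

Usage: python dicom_to_raw.py <series_dir> <out_prefix>

Writes <out_prefix>.raw (little-endian float32, Fortran order) and
<out_prefix>.json with {"dim": [ap, lr, cc], "spacing": [mm, mm, mm]}.
The array is re-oriented so axis 0 is anterior-posterior (anterior first),
axis 1 left-right, axis 2 cranio-caudal (slices sorted by position).
Exits non-zero with a message on stderr for mixed series or missing tags.
"""
import json
import sys

import numpy as np
import pydicom


def fail(msg):
    sys.stderr.write(msg + "\n")
    sys.exit(1)


def main(series_dir, out_prefix):
    import os
    files = sorted(
        os.path.join(series_dir, f)
        for f in os.listdir(series_dir)
        if not f.startswith(".")
    )
    if not files:
        fail("no files in directory")
    slices = []
    for f in files:
        try:
            ds = pydicom.dcmread(f)
        except Exception as e:  # noqa: BLE001
            fail("unreadable DICOM file %s: %s" % (f, e))
        slices.append(ds)

    uids = {getattr(ds, "SeriesInstanceUID", None) for ds in slices}
    if len(uids) > 1:
        fail("mixed series: inconsistent SeriesInstanceUID")
    for tag in ("PixelSpacing", "ImagePositionPatient"):
        missing = [i for i, ds in enumerate(slices) if not hasattr(ds, tag)]
        if missing:
            fail("missing required tag %s in slice %d" % (tag, missing[0]))
    spacings = {tuple(float(x) for x in ds.PixelSpacing) for ds in slices}
    if len(spacings) > 1:
        fail("mixed series: inconsistent PixelSpacing across slices")
    shapes = {(int(ds.Rows), int(ds.Columns)) for ds in slices}
    if len(shapes) > 1:
        fail("mixed series: inconsistent Rows/Columns across slices")

    slices.sort(key=lambda ds: float(ds.ImagePositionPatient[2]))
    zs = [float(ds.ImagePositionPatient[2]) for ds in slices]
    dz = float(np.diff(zs).mean()) if len(zs) > 1 else float(
        getattr(slices[0], "SliceThickness", 1.0)
    )

    vols = []
    for ds in slices:
        arr = ds.pixel_array.astype(np.float64)
        slope = float(getattr(ds, "RescaleSlope", 1.0))
        intercept = float(getattr(ds, "RescaleIntercept", 0.0))
        vols.append(arr * slope + intercept)
    # stack: (cc, rows=AP, cols=LR) -> reorder to (AP, LR, CC)
    vol = np.stack(vols, axis=0).transpose(1, 2, 0)
    row_sp, col_sp = (float(x) for x in slices[0].PixelSpacing)
    spacing = [row_sp, col_sp, abs(dz)]

    vol.astype("<f4").ravel(order="F").tofile(out_prefix + ".raw")
    with open(out_prefix + ".json", "w") as fh:
        json.dump({"dim": list(vol.shape), "spacing": spacing}, fh)


if __name__ == "__main__":
    if len(sys.argv) != 3:
        fail("usage: dicom_to_raw.py <series_dir> <out_prefix>")
    main(sys.argv[1], sys.argv[2])
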