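"""HDF5 bridge for per-slice MATLAB v7.3 tumor files (cjdata layout).

Invoked by the R package through the system `python`; exchanges images
with R via a raw float64 binary plus a CSV manifest. A MATLAB matrix of
shape (h, w) appears in the HDF5 file as a dataset of shape (w, h); its
C-order bytes are exactly the column-major bytes of the (h, w) matrix,
which is what R's readBin/writeBin produce. No reshaping is done on the
byte stream on either side.

Modes:
  read  <dir> <out_meta.csv> <out_images.bin>
  write <dir> <meta.csv> <images.bin>
"""
import csv
import os
import sys

import h5py
import numpy as np

REQUIRED = ("image", "label", "PID", "tumorBorder", "tumorMask")


def _scalar(ds):
    return float(np.asarray(ds).flatten()[0])


def _pid(ds):
    arr = np.asarray(ds).flatten()
    if arr.dtype.kind in "ui" or arr.dtype.kind == "f":
        return "".join(chr(int(c)) for c in arr)
    return arr.tobytes().decode("utf-8", "replace")


def read_dir(src, meta_path, bin_path):
    files = sorted(
        f for f in os.listdir(src) if f.lower().endswith(".mat"))
    with open(meta_path, "w", newline="") as mf, open(bin_path, "wb") as bf:
        wr = csv.writer(mf)
        wr.writerow(["file", "status", "label", "pid", "h", "w",
                     "border_len", "has_mask"])
        for name in files:
            path = os.path.join(src, name)
            try:
                with h5py.File(path, "r") as f:
                    if "cjdata" not in f:
                        wr.writerow([name, "error:missing cjdata",
                                     "", "", "", "", "", ""])
                        continue
                    cj = f["cjdata"]
                    missing = [k for k in REQUIRED if k not in cj]
                    if missing:
                        wr.writerow(
                            [name, "error:missing field " + missing[0],
                             "", "", "", "", "", ""])
                        continue
                    img = np.asarray(cj["image"], dtype=np.float64)
                    w, h = img.shape  # stored transposed: (w, h)
                    label = int(_scalar(cj["label"]))
                    pid = _pid(cj["PID"])
                    border_len = int(np.asarray(cj["tumorBorder"]).size)
                    has_mask = int(np.asarray(cj["tumorMask"]).size > 0)
                    img.tofile(bf)
                    wr.writerow([name, "ok", label, pid, h, w,
                                 border_len, has_mask])
            except OSError:
                wr.writerow([name, "error:not an HDF5 file",
                             "", "", "", "", "", ""])


def write_dir(dst, meta_path, bin_path):
    os.makedirs(dst, exist_ok=True)
    with open(meta_path, newline="") as mf, open(bin_path, "rb") as bf:
        for row in csv.DictReader(mf):
            h, w = int(row["h"]), int(row["w"])
            flat = np.fromfile(bf, dtype=np.float64, count=h * w)
            img_t = flat.reshape(w, h)  # MATLAB-style transposed storage
            with h5py.File(os.path.join(dst, row["file"]), "w") as f:
                cj = f.create_group("cjdata")
                cj.create_dataset("image", data=img_t)
                cj.create_dataset(
                    "label", data=np.array([[float(row["label"])]]))
                cj.create_dataset(
                    "PID",
                    data=np.array([[np.uint16(ord(c))] for c in row["pid"]]))
                cj.create_dataset("tumorBorder", data=np.zeros((2, 1)))
                cj.create_dataset(
                    "tumorMask", data=np.zeros((w, h), dtype=np.uint8))


def main():
    mode = sys.argv[1]
    if mode == "read":
        read_dir(sys.argv[2], sys.argv[3], sys.argv[4])
    elif mode == "write":
        write_dir(sys.argv[2], sys.argv[3], sys.argv[4])
    else:
        raise SystemExit("unknown mode: " + mode)


if __name__ == "__main__":
    main()
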