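"""Extended-precision reference for the composite CBS extrapolation.

Reads a CSV with columns
  id,hf3,hf4,mp2_3,mp2_4,npno2,npno3,tpno2,alpha,beta
and writes id,composite evaluated with 50-digit arithmetic.

Usage: python cbs_oracle.py in.csv out.csv
"""
import csv
import sys

from mpmath import mp, mpf, exp, sqrt

mp.dps = 50


def composite(row):
    a = mpf(row["alpha"])
    b = mpf(row["beta"])
    w4 = exp(-a * sqrt(4))
    w3 = exp(-a * sqrt(3))
    hf = (w4 * mpf(row["hf3"]) - w3 * mpf(row["hf4"])) / (w4 - w3)
    c4 = mpf(4) ** b
    c3 = mpf(3) ** b
    corr = (c4 * mpf(row["mp2_4"]) - c3 * mpf(row["mp2_3"])) / (c4 - c3)
    return (hf + corr - mpf(row["mp2_3"]) + mpf(row["npno3"])
            + mpf(row["tpno2"]) - mpf(row["npno2"]))


def main(inp, outp):
    with open(inp) as fh, open(outp, "w", newline="") as out:
        writer = csv.writer(out)
        writer.writerow(["id", "composite"])
        for row in csv.DictReader(fh):
            writer.writerow([row["id"], mp.nstr(composite(row), 30)])


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
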