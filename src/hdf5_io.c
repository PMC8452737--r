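/* Minimal HDF5 bindings: flat (root-level) 1D/2D numeric datasets plus
 * scalar root attributes.  Dataset buffers cross the .Call boundary in C
 * (row-major) order; the R wrappers handle transposition. */

#include <hdf5.h>
#include <string.h>
#include <R.h>
#include <Rinternals.h>

static void h5_silence(void)
{
    H5Eset_auto2(H5E_DEFAULT, NULL, NULL);
}

static hid_t open_file_read(const char *path)
{
    htri_t is = H5Fis_hdf5(path);
    if (is <= 0)
        Rf_error("'%s' is not a readable HDF5 file", path);
    hid_t fid = H5Fopen(path, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (fid < 0)
        Rf_error("failed to open HDF5 file '%s'", path);
    return fid;
}

/* ---- write --------------------------------------------------------- */

static void write_one_dataset(hid_t fid, const char *name, SEXP obj,
                              const char *dtype)
{
    SEXP dimattr = Rf_getAttrib(obj, Rf_install("h5dim"));
    int rank = 1;
    hsize_t dims[2];
    if (dimattr != R_NilValue) {
        rank = Rf_length(dimattr);
        if (rank < 1 || rank > 2)
            Rf_error("dataset '%s': only rank 1 or 2 supported", name);
        for (int i = 0; i < rank; i++)
            dims[i] = (hsize_t) INTEGER(dimattr)[i];
    } else {
        dims[0] = (hsize_t) Rf_xlength(obj);
    }

    hid_t ftype;
    if (strcmp(dtype, "float64") == 0)      ftype = H5T_IEEE_F64LE;
    else if (strcmp(dtype, "float32") == 0) ftype = H5T_IEEE_F32LE;
    else if (strcmp(dtype, "int32") == 0)   ftype = H5T_STD_I32LE;
    else Rf_error("dataset '%s': unknown dtype '%s'", name, dtype);

    hid_t sid = H5Screate_simple(rank, dims, NULL);
    hid_t did = H5Dcreate2(fid, name, ftype, sid, H5P_DEFAULT, H5P_DEFAULT,
                           H5P_DEFAULT);
    if (did < 0) {
        H5Sclose(sid);
        Rf_error("failed to create dataset '%s'", name);
    }
    herr_t st;
    if (TYPEOF(obj) == INTSXP)
        st = H5Dwrite(did, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                      INTEGER(obj));
    else
        st = H5Dwrite(did, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                      REAL(obj));
    H5Dclose(did);
    H5Sclose(sid);
    if (st < 0)
        Rf_error("failed to write dataset '%s'", name);
}

static void write_one_attr(hid_t fid, const char *name, SEXP value)
{
    hid_t root = H5Gopen2(fid, "/", H5P_DEFAULT);
    hid_t sid = H5Screate(H5S_SCALAR);
    hid_t aid = -1;
    herr_t st = -1;

    if (TYPEOF(value) == STRSXP) {
        const char *s = CHAR(STRING_ELT(value, 0));
        hid_t stype = H5Tcopy(H5T_C_S1);
        H5Tset_size(stype, strlen(s) + 1);
        H5Tset_strpad(stype, H5T_STR_NULLTERM);
        aid = H5Acreate2(root, name, stype, sid, H5P_DEFAULT, H5P_DEFAULT);
        if (aid >= 0) st = H5Awrite(aid, stype, s);
        H5Tclose(stype);
    } else if (TYPEOF(value) == INTSXP || TYPEOF(value) == LGLSXP) {
        int v = TYPEOF(value) == INTSXP ? INTEGER(value)[0] : LOGICAL(value)[0];
        aid = H5Acreate2(root, name, H5T_STD_I32LE, sid, H5P_DEFAULT,
                         H5P_DEFAULT);
        if (aid >= 0) st = H5Awrite(aid, H5T_NATIVE_INT, &v);
    } else if (TYPEOF(value) == REALSXP) {
        double v = REAL(value)[0];
        aid = H5Acreate2(root, name, H5T_IEEE_F64LE, sid, H5P_DEFAULT,
                         H5P_DEFAULT);
        if (aid >= 0) st = H5Awrite(aid, H5T_NATIVE_DOUBLE, &v);
    }
    if (aid >= 0) H5Aclose(aid);
    H5Sclose(sid);
    H5Gclose(root);
    if (st < 0)
        Rf_error("failed to write attribute '%s'", name);
}

SEXP C_h5_write(SEXP path, SEXP names, SEXP objects, SEXP dtypes,
                SEXP attr_names, SEXP attr_values)
{
    h5_silence();
    const char *cpath = CHAR(STRING_ELT(path, 0));
    hid_t fid = H5Fcreate(cpath, H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
    if (fid < 0)
        Rf_error("cannot create HDF5 file '%s' (unwritable path?)", cpath);

    R_xlen_t n = Rf_xlength(names);
    for (R_xlen_t i = 0; i < n; i++)
        write_one_dataset(fid, CHAR(STRING_ELT(names, i)),
                          VECTOR_ELT(objects, i),
                          CHAR(STRING_ELT(dtypes, i)));

    R_xlen_t na = Rf_xlength(attr_names);
    for (R_xlen_t i = 0; i < na; i++)
        write_one_attr(fid, CHAR(STRING_ELT(attr_names, i)),
                       VECTOR_ELT(attr_values, i));

    H5Fclose(fid);
    return path;
}

/* ---- read ---------------------------------------------------------- */

SEXP C_h5_ls(SEXP path)
{
    h5_silence();
    hid_t fid = open_file_read(CHAR(STRING_ELT(path, 0)));
    hid_t root = H5Gopen2(fid, "/", H5P_DEFAULT);
    H5G_info_t info;
    H5Gget_info(root, &info);

    SEXP out = PROTECT(Rf_allocVector(STRSXP, (R_xlen_t) info.nlinks));
    char buf[512];
    for (hsize_t i = 0; i < info.nlinks; i++) {
        H5Lget_name_by_idx(root, ".", H5_INDEX_NAME, H5_ITER_INC, i, buf,
                           sizeof(buf), H5P_DEFAULT);
        SET_STRING_ELT(out, (R_xlen_t) i, Rf_mkChar(buf));
    }
    H5Gclose(root);
    H5Fclose(fid);
    UNPROTECT(1);
    return out;
}

SEXP C_h5_read(SEXP path, SEXP name)
{
    h5_silence();
    const char *cpath = CHAR(STRING_ELT(path, 0));
    const char *cname = CHAR(STRING_ELT(name, 0));
    hid_t fid = open_file_read(cpath);

    if (H5Lexists(fid, cname, H5P_DEFAULT) <= 0) {
        H5Fclose(fid);
        Rf_error("HDF5 file '%s' has no dataset '%s'", cpath, cname);
    }
    hid_t did = H5Dopen2(fid, cname, H5P_DEFAULT);
    if (did < 0) {
        H5Fclose(fid);
        Rf_error("failed to open dataset '%s'", cname);
    }
    hid_t sid = H5Dget_space(did);
    int rank = H5Sget_simple_extent_ndims(sid);
    if (rank < 1 || rank > 2) {
        H5Sclose(sid); H5Dclose(did); H5Fclose(fid);
        Rf_error("dataset '%s': only rank 1 or 2 supported", cname);
    }
    hsize_t dims[2] = {1, 1};
    H5Sget_simple_extent_dims(sid, dims, NULL);
    R_xlen_t ntot = (R_xlen_t) dims[0] * (rank == 2 ? (R_xlen_t) dims[1] : 1);

    hid_t dtype = H5Dget_type(did);
    H5T_class_t cls = H5Tget_class(dtype);

    SEXP data;
    herr_t st;
    if (cls == H5T_INTEGER) {
        data = PROTECT(Rf_allocVector(INTSXP, ntot));
        st = H5Dread(did, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                     INTEGER(data));
    } else {
        data = PROTECT(Rf_allocVector(REALSXP, ntot));
        st = H5Dread(did, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                     REAL(data));
    }
    H5Tclose(dtype);
    H5Sclose(sid);
    H5Dclose(did);
    H5Fclose(fid);
    if (st < 0)
        Rf_error("failed to read dataset '%s'", cname);

    SEXP rdims = PROTECT(Rf_allocVector(INTSXP, rank));
    for (int i = 0; i < rank; i++)
        INTEGER(rdims)[i] = (int) dims[i];

    SEXP out = PROTECT(Rf_allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, data);
    SET_VECTOR_ELT(out, 1, rdims);
    SEXP nm = PROTECT(Rf_allocVector(STRSXP, 2));
    SET_STRING_ELT(nm, 0, Rf_mkChar("data"));
    SET_STRING_ELT(nm, 1, Rf_mkChar("dims"));
    Rf_setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(4);
    return out;
}

SEXP C_h5_read_attrs(SEXP path)
{
    h5_silence();
    hid_t fid = open_file_read(CHAR(STRING_ELT(path, 0)));
    hid_t root = H5Gopen2(fid, "/", H5P_DEFAULT);

    H5O_info2_t oinfo;
    H5Oget_info3(root, &oinfo, H5O_INFO_NUM_ATTRS);
    R_xlen_t na = (R_xlen_t) oinfo.num_attrs;

    SEXP out = PROTECT(Rf_allocVector(VECSXP, na));
    SEXP nms = PROTECT(Rf_allocVector(STRSXP, na));

    for (R_xlen_t i = 0; i < na; i++) {
        char buf[512];
        hid_t aid = H5Aopen_by_idx(root, ".", H5_INDEX_NAME, H5_ITER_INC,
                                   (hsize_t) i, H5P_DEFAULT, H5P_DEFAULT);
        H5Aget_name(aid, sizeof(buf), buf);
        SET_STRING_ELT(nms, i, Rf_mkChar(buf));

        hid_t atype = H5Aget_type(aid);
        H5T_class_t cls = H5Tget_class(atype);
        if (cls == H5T_STRING) {
            size_t sz = H5Tget_size(atype);
            char *sbuf = (char *) R_alloc(sz + 1, 1);
            memset(sbuf, 0, sz + 1);
            if (H5Tis_variable_str(atype) > 0) {
                char *vstr = NULL;
                hid_t mtype = H5Tcopy(H5T_C_S1);
                H5Tset_size(mtype, H5T_VARIABLE);
                if (H5Aread(aid, mtype, &vstr) >= 0 && vstr != NULL) {
                    SET_VECTOR_ELT(out, i, Rf_ScalarString(Rf_mkChar(vstr)));
                    H5free_memory(vstr);
                } else {
                    SET_VECTOR_ELT(out, i, Rf_ScalarString(Rf_mkChar("")));
                }
                H5Tclose(mtype);
            } else {
                hid_t mtype = H5Tcopy(H5T_C_S1);
                H5Tset_size(mtype, sz + 1);
                H5Aread(aid, mtype, sbuf);
                H5Tclose(mtype);
                SET_VECTOR_ELT(out, i, Rf_ScalarString(Rf_mkChar(sbuf)));
            }
        } else if (cls == H5T_INTEGER) {
            int v = 0;
            H5Aread(aid, H5T_NATIVE_INT, &v);
            SET_VECTOR_ELT(out, i, Rf_ScalarInteger(v));
        } else {
            double v = 0;
            H5Aread(aid, H5T_NATIVE_DOUBLE, &v);
            SET_VECTOR_ELT(out, i, Rf_ScalarReal(v));
        }
        H5Tclose(atype);
        H5Aclose(aid);
    }
    Rf_setAttrib(out, R_NamesSymbol, nms);
    H5Gclose(root);
    H5Fclose(fid);
    UNPROTECT(2);
    return out;
}
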